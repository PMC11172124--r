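#' @export
`[.radial_profiles` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "K") <- attr(x, "K")
    class(out) <- c("radial_profiles", "data.frame")
  }
  out
}
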