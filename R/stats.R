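#' Aggregate shell profiles into regions of interest
#'
#' Blocks of `ro_size` consecutive layers form one region of interest (RO):
#' RO `r` covers layers `(r-1)*ro_size + 1 ... r*ro_size`, so with the
#' default `K = 24`, `ro_size = 4` there are six ROs, RO-1 the innermost
#' layers 1-4 and RO-6 the outermost layers 21-24. The per-nucleus RO value
#' is the voxel-count-weighted mean of that nucleus's layer means in the
#' range (equal to total intensity over total voxels, so the weighted mean
#' over all ROs reproduces the whole-nucleus mean). Group statistics (mean,
#' SEM = sd/sqrt(n), n) are computed across nuclei within each condition;
#' the nucleus, not the voxel, is the statistical unit. With a single
#' nucleus the convention sd = 0 gives SEM = 0.
#'
#' @param profiles a `radial_profiles` data frame (one or more images; see
#'   [bind_profiles()]).
#' @param ro_size layers per RO; must divide `K`.
#' @return An `ro_summary`: list with `$per_nucleus` (one row per nucleus
#'   and RO) and `$summary` (one row per condition and RO with `mean`,
#'   `sem`, `n`, `layer_lo`, `layer_hi`).
#' @export
aggregate_ro <- function(profiles, ro_size = 4) {
  stopifnot(inherits(profiles, "radial_profiles"))
  K <- attr(profiles, "K") %||% max(profiles$layer)
  if (K %% ro_size != 0)
    ns_stop(sprintf("ro_size %d does not divide K = %d", ro_size, K),
            "validation_error")
  df <- as.data.frame(profiles)
  df$ro_index <- (df$layer - 1L) %/% ro_size + 1L
  df$total <- ifelse(df$voxel_count > 0, df$mean_intensity * df$voxel_count, 0)
  key <- interaction(df$source_id, df$nucleus_id, df$condition, df$ro_index,
                     drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(source_id = g$source_id[1], nucleus_id = g$nucleus_id[1],
               condition = g$condition[1], ro_index = g$ro_index[1],
               value = sum(g$total) / sum(g$voxel_count),
               voxel_count = sum(g$voxel_count),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$condition, agg$source_id, agg$nucleus_id,
                   agg$ro_index), ]
  summ <- do.call(rbind, lapply(
    split(agg, list(agg$condition, agg$ro_index), drop = TRUE),
    function(g) {
      n <- nrow(g)
      s <- if (n > 1) sd(g$value) else 0
      data.frame(condition = g$condition[1], ro_index = g$ro_index[1],
                 layer_lo = (g$ro_index[1] - 1L) * ro_size + 1L,
                 layer_hi = g$ro_index[1] * ro_size,
                 mean = mean(g$value), sem = s / sqrt(n), n = n,
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$condition, summ$ro_index), ]
  structure(list(per_nucleus = agg, summary = summ,
                 K = K, ro_size = as.integer(ro_size)),
            class = "ro_summary")
}

#' @export
print.ro_summary <- function(x, ...) {
  cat(sprintf("<ro_summary> K = %d, ro_size = %d\n", x$K, x$ro_size))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fold change between two RO group means
#'
#' Ratio of the group mean of `ro_to` over that of `ro_from` within one
#' condition -- e.g. the periphery-to-centre enrichment RO-6 / RO-1.
#'
#' @param ro an `ro_summary` from [aggregate_ro()].
#' @param ro_from,ro_to RO indices (defaults 1 and 6).
#' @param condition which condition to use; defaults to the only one
#'   present (an error if ambiguous).
#' @return A single numeric ratio.
#' @export
fold_change <- function(ro, ro_from = 1, ro_to = 6, condition = NULL) {
  stopifnot(inherits(ro, "ro_summary"))
  s <- ro$summary
  if (is.null(condition)) {
    conds <- unique(s$condition)
    if (length(conds) > 1L)
      ns_stop("several conditions present; specify `condition`",
              "validation_error")
    condition <- conds
  }
  m_from <- s$mean[s$condition == condition & s$ro_index == ro_from]
  m_to <- s$mean[s$condition == condition & s$ro_index == ro_to]
  if (length(m_from) != 1L || length(m_to) != 1L)
    ns_stop("requested RO not present in summary", "validation_error")
  if (m_from == 0)
    ns_stop("zero denominator in fold change", "degenerate_error")
  m_to / m_from
}

#' Compare two groups of nuclei per layer or per RO
#'
#' Runs a two-sided two-sample t-test (pooled-variance "Student's unpaired"
#' by default; Welch via `var_equal = FALSE`) on per-nucleus values for
#' every layer or RO. For `unit = "layer"` the per-nucleus value is the
#' layer mean intensity; missing (empty) layers are dropped pairwise. For
#' `unit = "RO"` per-nucleus RO values from [aggregate_ro()] are used. No
#' multiple-testing correction is applied by default; set
#' `p_adjust = "holm"` to correct across units.
#'
#' @param profiles_a,profiles_b `radial_profiles` for the two groups, each
#'   with at least 2 nuclei.
#' @param unit `"RO"` or `"layer"`.
#' @param alpha significance level for the flag (default 0.05).
#' @param ro_size layers per RO when `unit = "RO"`.
#' @param var_equal pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @param p_adjust p-value adjustment method (`"none"` default; any method
#'   of [stats::p.adjust()]).
#' @param labels length-2 character vector naming the groups.
#' @return A `group_comparison` data frame: one row per unit with group
#'   means, SEMs, `n_a`, `n_b`, `t`, `p`, `significant`. The `t` statistic
#'   is oriented as group A minus group B.
#' @export
compare_groups <- function(profiles_a, profiles_b, unit = c("RO", "layer"),
                           alpha = 0.05, ro_size = 4, var_equal = TRUE,
                           p_adjust = "none",
                           labels = c(profiles_a$condition[1],
                                      profiles_b$condition[1])) {
  unit <- match.arg(unit)
  vals <- lapply(list(profiles_a, profiles_b), function(p) {
    stopifnot(inherits(p, "radial_profiles"))
    if (unit == "RO") {
      pn <- aggregate_ro(p, ro_size)$per_nucleus
      split(pn$value, pn$ro_index)
    } else {
      df <- as.data.frame(p)
      df <- df[df$voxel_count > 0, ]
      split(df$mean_intensity, df$layer)
    }
  })
  n_nuc <- vapply(list(profiles_a, profiles_b), function(p)
    length(unique(paste(p$source_id, p$nucleus_id))), integer(1))
  if (any(n_nuc < 2))
    ns_stop("each group needs >= 2 nuclei for a defined variance",
            "insufficient_replicates_error")
  units <- sort(as.integer(union(names(vals[[1]]), names(vals[[2]]))))
  rows <- lapply(units, function(u) {
    a <- vals[[1]][[as.character(u)]]
    b <- vals[[2]][[as.character(u)]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(unit = unit, index = u,
                        mean_a = if (length(a)) mean(a) else NA_real_,
                        mean_b = if (length(b)) mean(b) else NA_real_,
                        sem_a = NA_real_, sem_b = NA_real_,
                        n_a = length(a), n_b = length(b),
                        t = NA_real_, p = NA_real_, significant = NA))
    tt <- t.test(a, b, var.equal = var_equal)
    data.frame(unit = unit, index = u,
               mean_a = mean(a), mean_b = mean(b),
               sem_a = sd(a) / sqrt(length(a)), sem_b = sd(b) / sqrt(length(b)),
               n_a = length(a), n_b = length(b),
               t = unname(tt$statistic), p = tt$p.value,
               significant = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p <= alpha
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- labels
  class(out) <- c("group_comparison", "data.frame")
  out
}
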