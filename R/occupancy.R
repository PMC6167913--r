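SS_CATEGORIES <- c("Beta", "Helix", "Turn", "Coil")

# frame x 4 matrix of per-frame category counts over selected residues
frame_category_counts <- function(assignment, residues = NULL) {
  cat_mat <- assignment$category
  if (!is.null(residues)) {
    cat_mat <- cat_mat[, residues, drop = FALSE]
  }
  counts <- sapply(SS_CATEGORIES, function(k) rowSums(cat_mat == k))
  matrix(counts, nrow = nrow(cat_mat), ncol = 4,
         dimnames = list(NULL, SS_CATEGORIES))
}

resolve_region <- function(assignment, region) {
  if (is.null(region)) return(seq_len(ncol(assignment$category)))
  if (is.numeric(region)) {
    idx <- as.integer(region)
  } else {
    # "H:95-102" style: chain plus inclusive residue-number range
    m <- stringr::str_match(region, "^([A-Za-z]):(\\d+)-(\\d+)$")
    if (is.na(m[1, 1])) {
      abort("region must be residue indices or 'chain:from-to'",
            class = "abloopr_input_error")
    }
    r <- assignment$residues
    idx <- which(r$chain == m[1, 2] &
                 r$resno >= as.integer(m[1, 3]) &
                 r$resno <= as.integer(m[1, 4]))
  }
  if (length(idx) == 0 || any(idx < 1 | idx > ncol(assignment$category))) {
    abort("region selects no residues of the assignment",
          class = "abloopr_input_error")
  }
  idx
}

#' Secondary-structure occupancy with bootstrap confidence intervals
#'
#' For each of the four categories, the occupancy is the fraction of
#' (frame, residue) observations in the region assigned to that category,
#' normalised over frames times residues.  Confidence intervals come from a
#' seeded frame-level bootstrap (percentile method).
#'
#' @param assignment An `ss_assignment`.
#' @param region Residue selection: `NULL` (all residues), integer indices,
#'   or a `"chain:from-to"` residue-number range.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return A tibble of class `ss_occupancy` with columns `category`,
#'   `probability`, `ci_lower`, `ci_upper` and attributes `n_frames`,
#'   `n_residues`.
#' @export
ss_occupancy <- function(assignment, region = NULL, n_boot = 100,
                         conf = 0.95, seed = 1) {
  stopifnot(inherits(assignment, "ss_assignment"))
  idx <- resolve_region(assignment, region)
  counts <- frame_category_counts(assignment, idx)
  nf <- nrow(counts)
  nr <- length(idx)
  prob <- colSums(counts) / (nf * nr)
  boot <- withr::with_seed(seed, {
    t(replicate(n_boot, {
      pick <- sample.int(nf, nf, replace = TRUE)
      colSums(counts[pick, , drop = FALSE]) / (nf * nr)
    }))
  })
  alpha <- (1 - conf) / 2
  lo <- apply(boot, 2, quantile, probs = alpha, names = FALSE)
  hi <- apply(boot, 2, quantile, probs = 1 - alpha, names = FALSE)
  out <- tibble(
    category = SS_CATEGORIES,
    probability = unname(prob),
    ci_lower = pmin(lo, unname(prob)),
    ci_upper = pmax(hi, unname(prob))
  )
  structure(out, class = c("ss_occupancy", class(out)),
            n_frames = nf, n_residues = nr, conf = conf)
}

#' Contrast secondary-structure occupancy between two ensemble groups
#'
#' Pools per-frame category counts within each group (frames weighted
#' equally), computes the category-wise relative difference
#' `100 * (p_a - p_b) / p_b` with group B as the reference, and attaches a
#' two-tailed p-value from a seeded bootstrap that resamples frames within
#' each group.  When the reference probability is zero the relative
#' difference is undefined and reported as `NA`.
#'
#' @param group_a,group_b Lists of `ss_assignment` objects (one per
#'   antibody/ensemble), or single assignments.
#' @param region_a,region_b Region selections applied to each assignment
#'   (see [ss_occupancy()]).
#' @param n_boot Bootstrap resamples for the p-value (default 10000).
#' @param seed Integer seed.
#' @return A tibble of class `ss_contrast` with columns `category`, `p_a`,
#'   `p_b`, `diff`, `rel_diff_pct`, `p_value`; attributes `n_frames_a`,
#'   `n_frames_b`.
#' @export
contrast_groups <- function(group_a, group_b, region_a = NULL,
                            region_b = NULL, n_boot = 10000, seed = 1) {
  as_counts <- function(group, region) {
    if (inherits(group, "ss_assignment")) group <- list(group)
    if (length(group) == 0) {
      abort("both groups must be non-empty", class = "abloopr_input_error")
    }
    do.call(rbind, purrr::map(group, function(a) {
      idx <- resolve_region(a, region)
      frame_category_counts(a, idx) / length(idx)  # per-frame fractions
    }))
  }
  ca <- as_counts(group_a, region_a)
  cb <- as_counts(group_b, region_b)
  pa <- colMeans(ca)
  pb <- colMeans(cb)
  obs_diff <- pa - pb
  boot <- withr::with_seed(seed, {
    na <- nrow(ca); nb <- nrow(cb)
    replicate(n_boot, {
      da <- colMeans(ca[sample.int(na, na, replace = TRUE), , drop = FALSE])
      db <- colMeans(cb[sample.int(nb, nb, replace = TRUE), , drop = FALSE])
      da - db
    })
  })
  # two-tailed bootstrap p: does the resampled difference distribution
  # exclude zero?
  pvals <- vapply(seq_along(SS_CATEGORIES), function(k) {
    d <- boot[k, ]
    p_lo <- (1 + sum(d <= 0)) / (1 + n_boot)
    p_hi <- (1 + sum(d >= 0)) / (1 + n_boot)
    min(1, 2 * min(p_lo, p_hi))
  }, numeric(1))
  out <- tibble(
    category = SS_CATEGORIES,
    p_a = unname(pa),
    p_b = unname(pb),
    diff = unname(obs_diff),
    rel_diff_pct = ifelse(pb > 0, 100 * unname(obs_diff) / unname(pb), NA_real_),
    p_value = pvals
  )
  structure(out, class = c("ss_contrast", class(out)),
            n_frames_a = nrow(ca), n_frames_b = nrow(cb), n_boot = n_boot)
}

#' Occupancy bar chart with confidence intervals
#'
#' @param object An `ss_occupancy` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ss_occupancy
#' @export
autoplot.ss_occupancy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$category,
                                       y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.2) +
    ggplot2::labs(x = NULL, y = "occupancy",
                  title = sprintf("Secondary-structure occupancy (%d frames)",
                                  attr(object, "n_frames"))) +
    ggplot2::theme_minimal()
}
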