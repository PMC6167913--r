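#' Minkowski distance between two vectors
#'
#' `(sum |a_i - b_i|^p)^(1/p)` for order `p >= 1`; `p = 2` is the Euclidean
#' distance.
#'
#' @param a,b Numeric vectors of equal length.
#' @param p Minkowski order (default 4, the order used throughout the
#'   package's clustering).
#' @return A single non-negative number.
#' @examples
#' minkowski_distance(c(1, 1, 0), c(0, 0, 0), p = 4)
#' @export
minkowski_distance <- function(a, b, p = 4) {
  if (length(a) != length(b)) {
    abort("vectors must have equal length", class = "abloopr_dimension_error")
  }
  stopifnot(p >= 1)
  sum(abs(a - b)^p)^(1 / p)
}

#' Hierarchical clustering of Kidera feature vectors
#'
#' Agglomerative clustering of antibodies in the 20-dimensional combined
#' Kidera space under the Minkowski metric of order `p` (default 4).
#' Linkage defaults to complete.  The result is deterministic given its
#' inputs and can be cut at any `k`.
#'
#' @param features A tibble from [kidera_encode()] (column `antibody_id`
#'   plus 20 numeric feature columns).
#' @param p Minkowski order.
#' @param k Number of clusters for the stored partition (default 3).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return An object of class `kidera_clust`: the `hclust` tree, the
#'   assignments at `k`, and the metric parameters.
#' @export
cluster_kidera <- function(features, p = 4, k = 3, linkage = "complete") {
  stopifnot(is.data.frame(features), "antibody_id" %in% names(features))
  if (nrow(features) < 2) {
    abort("need at least 2 feature vectors", class = "abloopr_input_error")
  }
  if (anyDuplicated(features$antibody_id)) {
    abort("duplicate antibody ids", class = "abloopr_input_error")
  }
  m <- as.matrix(features[, setdiff(names(features), "antibody_id")])
  rownames(m) <- features$antibody_id
  d <- dist(m, method = "minkowski", p = p)
  hc <- hclust(d, method = linkage)
  k <- min(k, nrow(m))
  assignments <- cutree(hc, k = k)
  structure(list(hclust = hc, assignments = assignments, k = k, p = p,
                 linkage = linkage),
            class = "kidera_clust")
}

#' @export
print.kidera_clust <- function(x, ...) {
  cat(sprintf("<kidera_clust> %d antibodies, Minkowski p=%g, %s linkage, k=%d\n",
              length(x$assignments), x$p, x$linkage, x$k))
  invisible(x)
}

#' Cluster assignments as a tibble
#'
#' @param x A `kidera_clust`.
#' @param k Optional cut different from the stored one.
#' @param ... Unused.
#' @return A tibble with `antibody_id` and `cluster`.
#' @method tidy kidera_clust
#' @export
tidy.kidera_clust <- function(x, k = NULL, ...) {
  a <- if (is.null(k)) x$assignments else cutree(x$hclust, k = k)
  tibble(antibody_id = names(a), cluster = unname(a))
}

#' One-line clustering summary
#'
#' @param x A `kidera_clust`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `k`, `p`, `linkage`, `max_height`.
#' @method glance kidera_clust
#' @export
glance.kidera_clust <- function(x, ...) {
  tibble(n = length(x$assignments), k = x$k, p = x$p, linkage = x$linkage,
         max_height = max(x$hclust$height))
}

#' Export a cluster dendrogram as Newick
#'
#' Branch lengths derive from the merge heights.
#'
#' @param x A `kidera_clust`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
cluster_newick <- function(x, path = NULL) {
  phy <- ape::as.phylo(x$hclust)
  s <- ape::write.tree(phy)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Phenotype enrichment of clusters
#'
#' Cross-tabulates a cluster partition against phenotype labels and reports,
#' to one decimal, the percentage of each phenotype captured by each cluster
#' (summing to 100% across clusters per phenotype) and the phenotype
#' composition of each cluster.
#'
#' @param clust A `kidera_clust` (or a tibble with `antibody_id`, `cluster`).
#' @param records A tibble with `id` and `phenotype`.
#' @param k Optional alternative cut.
#' @return A tibble of class `enrichment_report`: `cluster`, `phenotype`,
#'   `n`, `pct_of_phenotype`, `pct_of_cluster`.  If unknown phenotypes are
#'   present the report carries attribute `flagged = TRUE` and a warning is
#'   raised.
#' @export
enrichment <- function(clust, records, k = NULL) {
  asg <- if (inherits(clust, "kidera_clust")) tidy(clust, k = k) else clust
  lab <- records[, c("id", "phenotype")]
  d <- left_join(asg, lab, by = c(antibody_id = "id"))
  if (any(is.na(d$phenotype))) {
    abort("all clustered antibodies must be labelled",
          class = "abloopr_input_error")
  }
  flagged <- any(d$phenotype == "unknown")
  if (flagged) warn("unknown phenotypes present; enrichment flagged")
  grid <- tidyr::expand_grid(cluster = sort(unique(d$cluster)),
                             phenotype = unique(d$phenotype))
  counts <- count(d, .data$cluster, .data$phenotype, name = "n")
  out <- left_join(grid, counts, by = c("cluster", "phenotype")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    group_by(.data$phenotype) |>
    mutate(pct_of_phenotype = round(100 * .data$n / sum(.data$n), 1)) |>
    group_by(.data$cluster) |>
    mutate(pct_of_cluster = round(100 * .data$n / sum(.data$n), 1)) |>
    ungroup()
  structure(out, class = c("enrichment_report", class(out)), flagged = flagged)
}

#' Dendrogram plot of a Kidera clustering
#'
#' @param object A `kidera_clust`.
#' @param ... Unused.
#' @return A ggplot dendrogram with leaves labelled by antibody id.
#' @method autoplot kidera_clust
#' @export
autoplot.kidera_clust <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$order)
  # leaf x-positions in plotting order
  leaf_x <- setNames(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge)); node_y <- hc$height
  segs <- list()
  pos <- function(v) if (v < 0) c(leaf_x[[as.character(-v)]], 0) else
    c(node_x[v], node_y[v])
  for (m in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[m, 1]); b <- pos(hc$merge[m, 2])
    node_x[m] <- mean(c(a[1], b[1]))
    segs[[length(segs) + 1]] <- tibble(
      x = c(a[1], a[1], b[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], hc$height[m], hc$height[m]),
      yend = c(hc$height[m], hc$height[m], b[2])
    )
  }
  segs <- bind_rows(segs)
  labs <- tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL,
                  y = sprintf("merge height (Minkowski p=%g)", object$p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Length distribution bar chart
#'
#' @param object A `cdr_length_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cdr_length_distribution
#' @export
autoplot.cdr_length_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = attr(object, "mean"), linetype = 2) +
    ggplot2::labs(x = "CDR loop length (aa)", y = "count",
                  title = attr(object, "source_label")) +
    ggplot2::theme_minimal()
}
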