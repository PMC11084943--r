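#' Assemble the behavior matrix feeding the network stage
#'
#' Extracts the five network variables from a scores table: the gambling
#' score (RGT), the mean magazine latency (Lat, motivation for reward), the
#' discounting AUC (PDT), the social preference ratio (SP) and the
#' short-term social memory ratio (STM). Missing values are allowed and are
#' handled pairwise downstream.
#'
#' @param scores A scores data.frame as produced by [score_cohort()].
#' @param variables Named character vector mapping node names to score
#'   columns.
#' @return Numeric matrix, subjects in rows, nodes in columns.
#' @export
behavior_matrix <- function(scores,
                            variables = c(RGT = "rgt_score",
                                          Lat = "mean_latency",
                                          PDT = "auc",
                                          SP = "sp_ratio",
                                          STM = "stm_ratio")) {
  stopifnot(all(variables %in% names(scores)))
  m <- as.matrix(scores[, variables, drop = FALSE])
  colnames(m) <- names(variables)
  rownames(m) <- scores$subject_id
  m
}

#' Pairwise-complete Spearman correlation matrix
#'
#' For every variable pair, the rows complete on both variables are
#' mid-ranked and their Pearson correlation taken — the rank transform is
#' recomputed per pair, so missingness in one variable never distorts the
#' ranks of another. Pairs with fewer than 3 complete observations or with
#' a constant variable are `NA` with a warning.
#'
#' @param m Numeric matrix, subjects in rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(m), colnames(m))
  flagged <- FALSE
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cc <- stats::complete.cases(m[, i], m[, j])
      x <- m[cc, i]; y <- m[cc, j]
      if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
        out[i, j] <- out[j, i] <- NA_real_
        flagged <- TRUE
        next
      }
      out[i, j] <- out[j, i] <- stats::cor(rank(x), rank(y))
    }
  }
  if (flagged)
    warning("undefined correlation(s) flagged NA (constant variable or < 3 complete pairs)")
  out
}

#' Threshold a correlation matrix into a behavioral network
#'
#' Retains the edge between two nodes iff the absolute correlation strictly
#' exceeds `threshold`; edge weights keep their sign. The default threshold
#' of 0.28 follows the convention of displaying only meaningfully strong
#' rank correlations in behavioral networks.
#'
#' @param corr Symmetric correlation matrix with unit diagonal (`NA`
#'   entries yield no edge).
#' @param threshold Retention threshold in `[0, 1)` applied to `|r|`.
#' @return An object of class `behavior_network`: a list with `nodes`,
#'   `edges` (data.frame `from`, `to`, `weight`) and `threshold`.
#' @export
build_network <- function(corr, threshold = 0.28) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr)), na.rm = TRUE) > 1e-10)
    stop("a symmetric correlation matrix is required")
  if (max(abs(diag(corr) - 1)) > 1e-10) stop("unit diagonal required")
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  nodes <- colnames(corr) %||% paste0("V", seq_len(ncol(corr)))
  from <- character(0); to <- character(0); w <- numeric(0)
  k <- ncol(corr)
  for (i in seq_len(max(k - 1L, 0L))) {
    for (j in (i + 1L):k) {
      r <- corr[i, j]
      if (!is.na(r) && abs(r) > threshold) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j]); w <- c(w, r)
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "behavior_network")
}

#' Strength centrality of every node
#'
#' The strength of a node is the sum of the absolute weights of its retained
#' edges — centrality accounting for both the number and the weight of ties.
#' Isolated nodes have strength 0.
#'
#' @param net A [build_network()] result.
#' @return Named numeric vector of strengths, with the most central node in
#'   attribute `"most_central"`.
#' @export
strength_centrality <- function(net) {
  stopifnot(inherits(net, "behavior_network"))
  s <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    for (e in seq_len(nrow(net$edges))) {
      w <- abs(net$edges$weight[e])
      s[net$edges$from[e]] <- s[net$edges$from[e]] + w
      s[net$edges$to[e]] <- s[net$edges$to[e]] + w
    }
  }
  attr(s, "most_central") <- names(s)[which.max(s)]
  s
}

#' Subgroup behavioral networks
#'
#' Splits the cohort into analysis subgroups and builds one thresholded
#' Spearman network per subgroup. The default grouping mirrors the study
#' contrast: controls without poor decision makers, knockdowns without poor
#' decision makers, and knockdown poor decision makers. Subgroups with
#' fewer than 3 subjects are skipped with a log entry (no network can be
#' estimated for them).
#'
#' @param scores Scores table ([score_cohort()]).
#' @param subjects Subject metadata with `treatment` and the called class.
#' @param grouping Either `"default"` or a named list mapping group names to
#'   subject-id vectors.
#' @param threshold Edge retention threshold.
#' @return Named list of `behavior_network` objects; skipped groups are
#'   reported in attribute `"log"`.
#' @export
subgroup_networks <- function(scores, subjects, grouping = "default",
                              threshold = 0.28) {
  if (identical(grouping, "default")) {
    cls <- subjects$phenotype_called %||% subjects$dm_class
    if (is.null(cls))
      cls <- scores$dm_class[match(subjects$subject_id, scores$subject_id)]
    grouping <- list(
      wt_nonpdm = subjects$subject_id[subjects$treatment == "Tph2-wt" &
                                        !is.na(cls) & cls != "PDM"],
      kd_nonpdm = subjects$subject_id[subjects$treatment == "Tph2-kd" &
                                        !is.na(cls) & cls != "PDM"],
      kd_pdm = subjects$subject_id[subjects$treatment == "Tph2-kd" &
                                     !is.na(cls) & cls == "PDM"])
  }
  if (!is.list(grouping)) stop("unknown grouping")
  nets <- list(); log <- character(0)
  for (g in names(grouping)) {
    ids <- grouping[[g]]
    sub <- scores[scores$subject_id %in% ids, , drop = FALSE]
    if (nrow(sub) < 3L) {
      log <- c(log, sprintf(
        "subgroup '%s' skipped: %d subject(s), no network can be computed",
        g, nrow(sub)))
      next
    }
    bm <- behavior_matrix(sub)
    nets[[g]] <- build_network(suppressWarnings(spearman_matrix(bm)),
                               threshold = threshold)
  }
  attr(nets, "log") <- log
  nets
}

#' Convert to igraph / export GraphML
#'
#' @param net A `behavior_network`.
#' @param path Output file path.
#' @return `as_igraph()` returns an igraph graph with a `weight` edge
#'   attribute; `write_network_graphml()` writes it and returns `path`
#'   invisibly.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "behavior_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' @rdname as_igraph
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @export
print.behavior_network <- function(x, ...) {
  cat(sprintf("<behavior_network> %d nodes, %d edges (|r| > %.2f)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}
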