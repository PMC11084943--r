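test_that("Spearman matrix reproduces hand-computed values", {
  x <- 1:10
  expect_equal(spearman_matrix(cbind(a = x, b = x))["a", "b"], 1)
  expect_equal(spearman_matrix(cbind(a = x, b = rev(x)))["a", "b"], -1)
  # mid-rank Pearson oracle with ties: 4.5 / sqrt(22.5)
  m <- cbind(x = c(1, 2, 2, 4), y = c(1, 3, 2, 4))
  expect_equal(spearman_matrix(m)["x", "y"], 4.5 / sqrt(22.5),
               tolerance = 1e-12)
})

test_that("Spearman matrix equals the reference estimator on random tied tables", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    m <- cbind(a = sample(1:5, n, TRUE) + runif(n, 0, 0.01),
               b = sample(1:5, n, TRUE))
    if (sd(m[, 1]) == 0 || sd(m[, 2]) == 0) next
    expect_equal(spearman_matrix(m)["a", "b"],
                 stats::cor(m[, 1], m[, 2], method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("pairwise-complete handling re-ranks per pair", {
  set.seed(13)
  m <- cbind(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  m[1:5, "a"] <- NA
  sm <- spearman_matrix(m)
  cc <- stats::complete.cases(m[, "a"], m[, "b"])
  expect_equal(sm["a", "b"],
               stats::cor(m[cc, "a"], m[cc, "b"], method = "spearman"))
  # b-c pair unaffected by a's missingness
  expect_equal(sm["b", "c"],
               stats::cor(m[, "b"], m[, "c"], method = "spearman"))
  expect_warning(spearman_matrix(cbind(a = rep(1, 5), b = 1:5)), "constant")
})

test_that("network thresholding retains |r| strictly above threshold", {
  corr <- diag(3)
  dimnames(corr) <- list(c("A", "B", "C"), c("A", "B", "C"))
  corr["A", "B"] <- corr["B", "A"] <- 0.29
  corr["A", "C"] <- corr["C", "A"] <- -0.30
  corr["B", "C"] <- corr["C", "B"] <- 0.10
  net <- build_network(corr, threshold = 0.28)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "A C"))
  expect_equal(net$edges$weight[net$edges$to == "C"], -0.30)

  expect_equal(nrow(build_network(diag(3))$edges), 0)
  full <- matrix(0.5, 4, 4); diag(full) <- 1
  expect_equal(nrow(build_network(full, threshold = 0)$edges), 6)
  expect_error(build_network(corr, threshold = 1), "threshold")
  expect_error(build_network(matrix(c(1, 0.2, 0.3, 1), 2)), "symmetric")
})

test_that("raising the threshold never adds edges", {
  set.seed(17)
  for (i in 1:20) {
    z <- matrix(rnorm(40), 8)
    corr <- suppressWarnings(spearman_matrix(z))
    ths <- sort(runif(4, 0, 0.9))
    sizes <- vapply(ths, function(t) nrow(build_network(corr, t)$edges),
                    numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("strength centrality sums absolute incident weights", {
  corr <- diag(3)
  dimnames(corr) <- list(c("A", "B", "C"), c("A", "B", "C"))
  corr["A", "B"] <- corr["B", "A"] <- 0.5
  corr["A", "C"] <- corr["C", "A"] <- -0.4
  s <- strength_centrality(build_network(corr, 0.2))
  expect_equal(as.numeric(s[c("A", "B", "C")]), c(0.9, 0.5, 0.4))
  expect_equal(attr(s, "most_central"), "A")
  s0 <- strength_centrality(build_network(diag(3)))
  expect_true(all(s0 == 0))
})

test_that("strength equals brute-force summation on random graphs", {
  set.seed(23)
  for (i in 1:100) {
    corr <- diag(5)
    v <- runif(10, -1, 1)
    corr[upper.tri(corr)] <- v
    corr[lower.tri(corr)] <- t(corr)[lower.tri(corr)]
    dimnames(corr) <- list(letters[1:5], letters[1:5])
    thr <- runif(1, 0, 0.6)
    s <- strength_centrality(build_network(corr, thr))
    a <- abs(corr); diag(a) <- 0; a[a <= thr] <- 0
    expect_equal(as.numeric(s), unname(rowSums(a)[letters[1:5]]))
  }
})

test_that("networks are invariant to monotone transforms of raw scores", {
  set.seed(29)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(NULL, c("RGT", "Lat", "PDT", "SP", "STM")))
  n1 <- build_network(spearman_matrix(m))
  m2 <- m; m2[, "Lat"] <- exp(m2[, "Lat"]); m2[, "RGT"] <- m2[, "RGT"]^3
  n2 <- build_network(spearman_matrix(m2))
  expect_equal(n1$edges, n2$edges)
})

test_that("subgroup networks split, skip small groups, and export", {
  set.seed(37)
  n <- 30
  scores <- data.frame(
    subject_id = sprintf("R%03d", 1:n),
    rgt_score = runif(n, 0, 100), mean_latency = rlnorm(n),
    auc = runif(n), sp_ratio = rlnorm(n), stm_ratio = rlnorm(n))
  scores$dm_class <- classify_dm(scores$rgt_score)
  subjects <- data.frame(
    subject_id = scores$subject_id,
    treatment = rep(c("Tph2-wt", "Tph2-kd"), each = n / 2),
    phenotype_called = scores$dm_class)
  nets <- subgroup_networks(scores, subjects)
  expect_true(all(names(nets) %in% c("wt_nonpdm", "kd_nonpdm", "kd_pdm")))
  # singleton subgroup is skipped with a log entry
  subjects2 <- subjects
  subjects2$phenotype_called[subjects2$treatment == "Tph2-kd"] <- "GDM"
  subjects2$phenotype_called[nrow(subjects2)] <- "PDM"
  nets2 <- subgroup_networks(scores, subjects2)
  expect_false("kd_pdm" %in% names(nets2))
  expect_match(attr(nets2, "log"), "kd_pdm", all = FALSE)

  # graphml round trip through igraph
  f <- tempfile(fileext = ".graphml")
  net <- nets[[1]]
  write_network_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
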