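#' Permutation ANOVA with subject as error stratum
#'
#' Repeated-measures ANOVA for small, non-parametric behavioral data sets,
#' tested by permutation instead of the F distribution. The classical F
#' statistics come from a two-stratum (split-plot) decomposition:
#' between-subject terms are tested against the subject-to-subject variance
#' within between-factor cells, within-subject terms (the within factor and
#' its interactions with between factors) against the within-subject
#' residual. The reference distribution is built by (a) permuting whole
#' subjects' between-factor label tuples for between terms and (b) permuting
#' within-level labels independently inside each subject for within terms.
#' P-values use the add-one estimator `(1 + #\{F* >= F\}) / (1 + n
#' permutations)` and so are never exactly zero; results are deterministic
#' given `seed`.
#'
#' Replicated observations within a subject-by-within-level cell are
#' averaged before the decomposition. A response with zero variance yields
#' F = 0 and p = 1 for every term.
#'
#' @param data Data.frame in long format.
#' @param response Name of the numeric response column.
#' @param between Character vector of between-subject factor columns (each
#'   subject carries exactly one level of each); may be empty.
#' @param within Name of the within-subject factor column (every subject
#'   must have every level), or `NULL` for a between-only design.
#' @param subject Name of the subject identifier column.
#' @param n_permutations Number of permutations per stratum.
#' @param seed Integer seed (mandatory).
#' @return A data.frame of class `perm_anova` with columns `term`,
#'   `stratum`, `df1`, `df2`, `statistic` (F) and `p_value`; attributes
#'   carry the permutation count and seed.
#' @examples
#' d <- expand.grid(subject = factor(1:12), enc = factor(1:3))
#' d$grp <- factor(rep(rep(c("a", "b"), each = 6), 3))
#' d$y <- rnorm(36)
#' perm_anova(d, "y", between = "grp", within = "enc",
#'            subject = "subject", n_permutations = 199, seed = 1)
#' @export
perm_anova <- function(data, response, between = character(), within = NULL,
                       subject, n_permutations = 5000, seed) {
  stopifnot(is.data.frame(data), response %in% names(data),
            subject %in% names(data), all(between %in% names(data)),
            is.null(within) || within %in% names(data),
            n_permutations >= 1)
  if (missing(seed)) stop("a seed is mandatory for permutation methods")
  set.seed(as.integer(seed))

  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (b in between) d[[b]] <- factor(d[[b]])
  if (!is.null(within)) d[[within]] <- factor(d[[within]])
  y_all <- d[[response]]
  if (!is.numeric(y_all) || anyNA(y_all)) stop("response must be numeric without NAs")

  # one between-factor level tuple per subject
  subj_levels <- levels(d[[subject]])
  subj_tab <- unique(d[c(subject, between)])
  if (nrow(subj_tab) != length(subj_levels))
    stop("each subject must carry exactly one level of each between factor")
  subj_tab <- subj_tab[order(subj_tab[[subject]]), , drop = FALSE]

  if (length(between)) {
    cells <- interaction(subj_tab[between], drop = TRUE)
    if (length(subj_levels) < nlevels(cells) + 1L)
      stop("fewer subjects than between-factor cells")
  }

  # aggregate replicates: one observation per subject x within-level cell
  if (is.null(within)) {
    m <- tapply(y_all, d[[subject]], mean)[subj_levels]
    J <- 1L
  } else {
    cell <- table(d[[subject]], d[[within]])
    if (any(cell == 0L))
      stop("every subject must have every level of the within factor")
    agg <- tapply(y_all, list(d[[subject]], d[[within]]), mean)
    J <- ncol(agg)
    m <- rowMeans(agg)[subj_levels]
  }
  N <- length(subj_levels)

  res <- list()

  ## ---- between stratum ------------------------------------------------
  if (length(between)) {
    fb <- stats::as.formula(paste("~", paste(between, collapse = "*")))
    Xb <- stats::model.matrix(fb, subj_tab)
    eng_b <- .anova_engine(Xb, attr(Xb, "assign"),
                           attr(stats::terms(fb), "term.labels"))
    obs_b <- .anova_f(eng_b, as.numeric(m))
    cnt_b <- rep(0L, length(eng_b$terms))
    for (r in seq_len(n_permutations)) {
      fp <- .anova_f(eng_b, as.numeric(m)[sample.int(N)])
      cnt_b <- cnt_b + (fp$F >= obs_b$F - 1e-12)
    }
    res$between <- data.frame(
      term = eng_b$terms, stratum = "between",
      df1 = obs_b$df, df2 = obs_b$df_err, statistic = obs_b$F,
      p_value = (1 + cnt_b) / (1 + n_permutations),
      stringsAsFactors = FALSE)
  }

  ## ---- within stratum -------------------------------------------------
  if (!is.null(within)) {
    long <- data.frame(subject = factor(rep(subj_levels, each = J),
                                        levels = subj_levels),
                       w = factor(rep(colnames(agg), times = N),
                                  levels = colnames(agg)))
    for (b in between)
      long[[b]] <- subj_tab[[b]][match(long$subject, subj_tab[[subject]])]
    yv <- as.numeric(t(agg[subj_levels, , drop = FALSE]))

    bterms <- if (length(between))
      attr(stats::terms(stats::as.formula(
        paste("~", paste(between, collapse = "*")))), "term.labels")
    else character(0)
    wterms <- c("w", if (length(bterms)) paste0("w:", bterms))
    fw <- stats::as.formula(paste("~ subject +", paste(wterms, collapse = " + ")))
    Xw <- stats::model.matrix(fw, long)
    labs <- attr(stats::terms(fw), "term.labels")
    keep <- labs != "subject"
    eng_w <- .anova_engine(Xw, attr(Xw, "assign"), labs, test = keep)
    obs_w <- .anova_f(eng_w, yv)
    cnt_w <- rep(0L, length(eng_w$terms))
    blk <- rep(seq_len(N), each = J)
    for (r in seq_len(n_permutations)) {
      idx <- order(blk + stats::runif(N * J))   # within-subject shuffle
      fp <- .anova_f(eng_w, yv[idx])
      cnt_w <- cnt_w + (fp$F >= obs_w$F - 1e-12)
    }
    wi <- data.frame(
      term = sub("^w:", paste0(within, ":"), sub("^w$", within, eng_w$terms)),
      stratum = "within",
      df1 = obs_w$df, df2 = obs_w$df_err, statistic = obs_w$F,
      p_value = (1 + cnt_w) / (1 + n_permutations),
      stringsAsFactors = FALSE)
    res$within <- wi
  }

  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_subjects") <- N
  class(out) <- c("perm_anova", "data.frame")
  out
}

# precompute the QR of a sequential model matrix; map retained columns to
# terms so sums of squares can be read off the effects vector per permuted
# response
.anova_engine <- function(X, assign, term_labels, test = NULL) {
  qrx <- qr(X)
  rank <- qrx$rank
  piv <- qrx$pivot[seq_len(rank)]
  eff_term <- assign[piv]                    # term id per retained effect
  ids <- sort(unique(eff_term[eff_term > 0]))
  if (is.null(test)) test <- rep(TRUE, length(term_labels))
  keep <- ids[test[ids]]
  list(qr = qrx, rank = rank, n = nrow(X),
       eff_term = eff_term,
       term_ids = keep,
       terms = term_labels[keep],
       df = vapply(keep, function(k) sum(eff_term == k), integer(1)),
       df_err = nrow(X) - rank)
}

.anova_f <- function(eng, y) {
  qty <- qr.qty(eng$qr, y)
  eff <- qty[seq_len(eng$rank)]
  ss <- vapply(eng$term_ids, function(k) sum(eff[eng$eff_term == k]^2),
               numeric(1))
  rss <- sum(qty[-seq_len(eng$rank)]^2)
  mse <- if (eng$df_err > 0) rss / eng$df_err else 0
  if (mse <= 1e-12) {
    f <- rep(Inf, length(ss))
    f[ss <= 1e-12] <- 0
  } else {
    f <- (ss / eng$df) / mse
  }
  list(F = f, df = eng$df, df_err = eng$df_err)
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("Permutation ANOVA (%d permutations, seed %d, %d subjects)\n",
              attr(x, "n_permutations"), attr(x, "seed"),
              attr(x, "n_subjects")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  p.anova, %s, F(%d,%d) = %.3g, p = %.4g\n",
                x$term[i], x$df1[i], x$df2[i], x$statistic[i], x$p_value[i]))
  invisible(x)
}
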