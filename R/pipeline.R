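#' Pipeline configuration
#'
#' Bundles every tunable of the simulate / score / stats / network pipeline.
#' The configuration round-trips losslessly through JSON and is written next
#' to the outputs of every run together with its hash.
#'
#' @param seed Master seed; fans out deterministically to every stage.
#' @param out_dir Output directory of [run_pipeline()].
#' @param cohort A [cohort_config()] (stored as-is).
#' @param network_threshold Edge retention threshold of the network stage.
#' @param n_permutations Permutation count of the ANOVA stage.
#' @param fisher_table Which contingency table feeds the Fisher test;
#'   currently `"gdm_pdm"` (the 2x2 GDM/PDM table).
#' @param fisher_tail Tail of the Fisher test.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("rgtnet_run_"),
                            cohort = cohort_config(),
                            network_threshold = 0.28,
                            n_permutations = 5000L,
                            fisher_table = "gdm_pdm",
                            fisher_tail = "two.sided") {
  stopifnot(inherits(cohort, "cohort_config"),
            fisher_table %in% "gdm_pdm",
            fisher_tail %in% c("two.sided", "greater", "less"))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort = cohort,
                 network_threshold = network_threshold,
                 n_permutations = as.integer(n_permutations),
                 fisher_table = fisher_table, fisher_tail = fisher_tail),
            class = "pipeline_config")
}

# FNV-1a over the JSON serialization: a stable, dependency-free config hash
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(.serializable(config)), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

.serializable <- function(x) {
  if (inherits(x, "agent_params") || inherits(x, "cohort_config") ||
      inherits(x, "pipeline_config")) x <- unclass(x)
  if (is.list(x)) lapply(x, .serializable) else x
}

#' Group-level statistics of a scored cohort
#'
#' The inferential layer over a scored cohort, mirroring the analyses of a
#' gambling-task phenotyping study: rank-sum comparison of RGT scores
#' between arms; Fisher's exact test on the GDM/PDM contingency table;
#' Kruskal-Wallis on the discounting AUC across the six treatment-by-class
#' subgroups; signed-rank tests of the knockdown-PDM short-term memory
#' ratio against 1 and of the odor preference against 50%; and permutation
#' ANOVAs for the magazine latency (between factors: treatment, class), the
#' PDT preference over probability levels and the social-encounter
#' interaction times (within factor: encounter).
#'
#' @param scores,subjects Tables from [score_cohort()].
#' @param trials Trial table (needed for the PDT probability-level ANOVA);
#'   may be `NULL`.
#' @param srt Social-recognition durations (encounter ANOVA); may be `NULL`.
#' @param n_permutations,seed Permutation parameters.
#' @param fisher_tail Tail of the Fisher test.
#' @return Named list of [`dm_test`][new_dm_test] and [perm_anova()]
#'   results.
#' @export
cohort_stats <- function(scores, subjects, trials = NULL, srt = NULL,
                         n_permutations = 5000, seed = 1,
                         fisher_tail = "two.sided") {
  trt <- subjects$treatment[match(scores$subject_id, subjects$subject_id)]
  out <- list()

  ok <- !is.na(scores$rgt_score)
  if (any(ok & trt == "Tph2-wt") && any(ok & trt == "Tph2-kd")) {
    out$rgt_wt_vs_kd <- rank_sum(scores$rgt_score[ok & trt == "Tph2-wt"],
                                 scores$rgt_score[ok & trt == "Tph2-kd"])
    tb <- vapply(c("Tph2-wt", "Tph2-kd"), function(a)
      c(GDM = sum(scores$dm_class == "GDM" & trt == a, na.rm = TRUE),
        PDM = sum(scores$dm_class == "PDM" & trt == a, na.rm = TRUE)),
      numeric(2))
    tb <- t(tb)
    if (all(rowSums(tb) > 0) && all(colSums(tb) > 0))
      out$dm_proportions <- fisher_exact(tb, tail = fisher_tail)
  }

  grp <- interaction(trt, scores$dm_class, drop = TRUE)
  oka <- !is.na(scores$auc) & !is.na(grp)
  if (length(unique(grp[oka])) >= 2L)
    out$auc_by_subgroup <- kruskal(split(scores$auc[oka], droplevels(grp[oka])))

  kd_pdm <- trt == "Tph2-kd" & scores$dm_class == "PDM"
  v <- scores$stm_ratio[kd_pdm & !is.na(scores$stm_ratio)]
  if (length(v) >= 2L && !all(v == 1)) out$stm_vs_1_kd_pdm <- signed_rank_vs(v, 1)
  v <- scores$odor_pref[!is.na(scores$odor_pref)]
  if (length(v) >= 2L && !all(v == 50)) out$odor_vs_chance <- signed_rank_vs(v, 50)

  okl <- !is.na(scores$mean_latency) & !is.na(scores$dm_class)
  if (sum(okl) >= 8L) {
    dl <- data.frame(subject = scores$subject_id[okl],
                     y = scores$mean_latency[okl],
                     treatment = trt[okl], dm_class = scores$dm_class[okl])
    out$latency_anova <- perm_anova(dl, "y",
                                    between = c("treatment", "dm_class"),
                                    subject = "subject",
                                    n_permutations = n_permutations,
                                    seed = seed)
  }

  if (!is.null(trials) && any(trials$task == "PDT")) {
    pd <- .pdt_long(scores, subjects, trials)
    if (!is.null(pd))
      out$pdt_anova <- perm_anova(pd, "pref", between = "treatment",
                                  within = "probability", subject = "subject",
                                  n_permutations = n_permutations,
                                  seed = seed + 1)
  }

  if (!is.null(srt) && nrow(srt)) {
    sl <- stats::reshape(srt[c("subject_id", "hab", "e1", "e2", "e3")],
                         direction = "long",
                         varying = c("hab", "e1", "e2", "e3"),
                         v.names = "duration", timevar = "encounter",
                         times = c("Hab", "E1", "E2", "E3"),
                         idvar = "subject_id")
    sl$treatment <- subjects$treatment[match(sl$subject_id,
                                             subjects$subject_id)]
    out$srt_anova <- perm_anova(sl, "duration", between = "treatment",
                                within = "encounter", subject = "subject_id",
                                n_permutations = n_permutations,
                                seed = seed + 2)
  }
  out
}

# subject x probability preference table (first stable pair per level),
# complete cases only, for the repeated-measures ANOVA
.pdt_long <- function(scores, subjects, trials) {
  pdt <- trials[trials$task == "PDT", , drop = FALSE]
  rows <- lapply(split(pdt, pdt$subject_id), function(tr) {
    pr <- pdt_preferences(tr)
    data.frame(subject = tr$subject_id[1], probability = factor(pr$prob),
               pref = pr$pref, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d$treatment <- subjects$treatment[match(d$subject, subjects$subject_id)]
  complete <- tapply(!is.na(d$pref), d$subject, all)
  d <- d[complete[d$subject], , drop = FALSE]
  if (length(unique(d$subject)) < 6L) return(NULL)
  d
}

#' Run the full pipeline
#'
#' simulate -> score -> stats -> network, with fixed file contracts:
#' `subjects.csv`, `trials.csv`, `srt.csv`, `neurochem.csv`, `scores.csv`,
#' `stats.json`, `stats_report.txt`, per-subgroup `edges_<group>.csv`,
#' `strength_<group>.csv` and `network_<group>.graphml`, the resolved
#' `config.json` and a `run.log` with package version, seed and config
#' hash. Identical configuration and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the computed objects are
#'   attached as attributes `cohort`, `scores`, `stats`, `networks`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  cohort <- generate_cohort(config$cohort, seed = config$seed)
  sc <- score_cohort(cohort)
  stats <- cohort_stats(sc$scores, sc$subjects, cohort$trials, cohort$srt,
                        n_permutations = config$n_permutations,
                        seed = config$seed,
                        fisher_tail = config$fisher_tail)
  nets <- subgroup_networks(sc$scores, sc$subjects,
                            threshold = config$network_threshold)

  write_table <- function(d, f) utils::write.csv(d, out(f), row.names = FALSE)
  write_table(sc$subjects, "subjects.csv")
  write_table(cohort$trials, "trials.csv")
  write_table(cohort$srt, "srt.csv")
  write_table(cohort$neurochem, "neurochem.csv")
  write_table(sc$scores, "scores.csv")

  jsonlite::write_json(.stats_json(stats), out("stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(.stats_report(stats), out("stats_report.txt"))

  for (g in names(nets)) {
    write_table(nets[[g]]$edges, sprintf("edges_%s.csv", g))
    s <- strength_centrality(nets[[g]])
    write_table(data.frame(node = names(s), strength = as.numeric(s),
                           rank = rank(-as.numeric(s), ties.method = "min")),
                sprintf("strength_%s.csv", g))
    write_network_graphml(nets[[g]], out(sprintf("network_%s.graphml", g)))
  }

  jsonlite::write_json(unclass(.serializable(config)), out("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("rgtnet %s", as.character(utils::packageVersion("rgtnet"))),
    sprintf("seed: %d", config$seed),
    sprintf("config hash: %s", config_hash(config)),
    sprintf("subjects: %d, trials: %d", nrow(sc$subjects),
            nrow(cohort$trials)),
    attr(nets, "log")), out("run.log"))

  invisible(structure(config$out_dir, cohort = cohort, scores = sc$scores,
                      stats = stats, networks = nets))
}

.stats_json <- function(stats) {
  lapply(stats, function(s) {
    if (inherits(s, "dm_test"))
      list(method = s$method, statistic = s$statistic_name,
           value = s$statistic, p = s$p_value,
           n = as.numeric(s$n_per_group))
    else if (inherits(s, "perm_anova"))
      list(method = "permutation ANOVA",
           n_permutations = attr(s, "n_permutations"),
           seed = attr(s, "seed"),
           terms = lapply(seq_len(nrow(s)), function(i)
             list(term = s$term[i], df1 = s$df1[i], df2 = s$df2[i],
                  F = s$statistic[i], p = s$p_value[i])))
    else s
  })
}

.stats_report <- function(stats) {
  lines <- character(0)
  for (nm in names(stats)) {
    s <- stats[[nm]]
    if (inherits(s, "dm_test")) {
      lines <- c(lines, sprintf("%s: %s, %s = %.4g, p = %.4g", nm, s$method,
                                s$statistic_name, s$statistic, s$p_value))
    } else if (inherits(s, "perm_anova")) {
      for (i in seq_len(nrow(s)))
        lines <- c(lines, sprintf("%s: p.anova, %s, F(%d,%d) = %.3g, p = %.4g",
                                  nm, s$term[i], s$df1[i], s$df2[i],
                                  s$statistic[i], s$p_value[i]))
    }
  }
  lines
}

#' Command-line interface
#'
#' Subcommands `simulate`, `score`, `stats`, `network` and `run-all` over
#' the pipeline's CSV/JSON file contracts. `simulate` and `run-all` need
#' only `--out`; the downstream subcommands read the CSVs a previous stage
#' wrote into `--out`. An executable wrapper is installed under
#' `system.file("scripts", "rgtnet", package = "rgtnet")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
rgtnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rgtnet <simulate|score|stats|network|run-all>",
    "[--seed N] [--out DIR] [--threshold X] [--n-perm N]",
    "[--n-wt N] [--n-kd N]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- .parse_cli(args[-1])
  out_dir <- opts$out %||% "rgtnet_out"
  seed <- as.integer(opts$seed %||% 1L)
  thr <- as.numeric(opts$threshold %||% 0.28)
  nperm <- as.integer(opts$`n-perm` %||% 1000L)
  ccfg <- if (!is.null(opts$`n-wt`) || !is.null(opts$`n-kd`)) {
    nw <- as.integer(opts$`n-wt` %||% 60L); nk <- as.integer(opts$`n-kd` %||% 58L)
    scale_counts <- function(tot, ref) {
      x <- pmax(1L, as.integer(round(ref * tot / sum(ref))))
      x[1] <- x[1] + tot - sum(x)
      stats::setNames(x, names(ref))
    }
    cohort_config(n_wt = nw, n_kd = nk, phenotype_counts = list(
      wt = scale_counts(nw, c(GDM = 49L, INT = 8L, PDM = 3L)),
      kd = scale_counts(nk, c(GDM = 39L, INT = 10L, PDM = 9L))))
  } else cohort_config()

  read_tab <- function(f) utils::read.csv(file.path(out_dir, f),
                                          stringsAsFactors = FALSE)
  if (cmd == "run-all") {
    run_pipeline(pipeline_config(seed = seed, out_dir = out_dir,
                                 cohort = ccfg,
                                 network_threshold = thr,
                                 n_permutations = nperm))
  } else if (cmd == "simulate") {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cohort <- generate_cohort(ccfg, seed = seed)
    for (f in c("subjects", "trials", "srt", "neurochem"))
      utils::write.csv(cohort[[f]], file.path(out_dir, paste0(f, ".csv")),
                       row.names = FALSE)
  } else if (cmd == "score") {
    cohort <- list(subjects = read_tab("subjects.csv"),
                   trials = read_tab("trials.csv"),
                   srt = read_tab("srt.csv"),
                   neurochem = read_tab("neurochem.csv"))
    sc <- score_cohort(cohort)
    utils::write.csv(sc$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
  } else if (cmd == "stats") {
    st <- cohort_stats(read_tab("scores.csv"), read_tab("subjects.csv"),
                       read_tab("trials.csv"), read_tab("srt.csv"),
                       n_permutations = nperm, seed = seed)
    jsonlite::write_json(.stats_json(st), file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(.stats_report(st), file.path(out_dir, "stats_report.txt"))
  } else if (cmd == "network") {
    nets <- subgroup_networks(read_tab("scores.csv"), read_tab("subjects.csv"),
                              threshold = thr)
    for (g in names(nets))
      utils::write.csv(nets[[g]]$edges,
                       file.path(out_dir, sprintf("edges_%s.csv", g)),
                       row.names = FALSE)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}

.parse_cli <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  opts
}
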