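# Batch orchestration over directories of reconstructions, plus the
# group-comparison reporting utility.

#' Run the analysis pipeline over a set of reconstructions
#'
#' Reads each input (SWC or hoc, decided by extension), validates it
#' (files failing validation are skipped with a logged error; the run
#' continues), computes the per-neuron summary plus long-format
#' distributions, and optionally the subtree bootstrap and an MST sweep.
#' Outputs are a pure function of (input files, config, seeds).
#'
#' @param config list with elements \code{inputs} (character paths),
#'   optional \code{cellTypes} (parallel labels from GM/LG/LP/PD/
#'   synthetic/other), \code{outDir}, \code{seed} (default 1),
#'   \code{shollBins} (default 100), \code{analyses} (subset of
#'   \code{c("summary", "distributions", "subtrees", "mst")}; default
#'   the first two), \code{scrambles} (default 2000), \code{autoTagAxons}
#'   (default TRUE: tag reported axon candidates so subtree analyses are
#'   defined on plain SWC inputs).
#' @return list with \code{summaries} (data.frame, one row per neuron),
#'   \code{distributions} (long data.frame of path metrics),
#'   \code{subtrees}, \code{mst} (lists or NULL), \code{skipped}
#'   (character), \code{provenance}. When \code{outDir} is given,
#'   \code{summary.csv}, \code{distributions.csv}, per-neuron JSON and
#'   \code{provenance.json} are written there.
#' @export
runAnalysis <- function(config) {
  stopifnot(is.list(config), length(config$inputs) >= 1)
  inputs <- config$inputs
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  cellTypes <- config$cellTypes %||% rep("other", length(inputs))
  stopifnot(length(cellTypes) == length(inputs),
            all(cellTypes %in% .CELL_TYPES))
  seed <- config$seed %||% 1L
  shollBins <- config$shollBins %||% 100L
  analyses <- config$analyses %||% c("summary", "distributions")
  scrambles <- config$scrambles %||% 2000L
  autoTag <- config$autoTagAxons %||% TRUE

  summaries <- list(); dists <- list(); subResults <- list()
  mstResults <- list(); skipped <- character(); log <- character()
  for (i in seq_along(inputs)) {
    f <- inputs[i]
    g <- tryCatch({
      if (grepl("\\.hoc$", f, ignore.case = TRUE))
        parseHoc(f, cellType = cellTypes[i], isFile = TRUE)
      else parseSWC(f, cellType = cellTypes[i], isFile = TRUE)
    }, error = function(e) e)
    if (inherits(g, "error")) {
      skipped <- c(skipped, f)
      log <- c(log, paste0("SKIP ", f, ": ", conditionMessage(g)))
      next
    }
    rep <- validateGeometry(g)
    if (length(rep)) {
      skipped <- c(skipped, f)
      log <- c(log, paste0("SKIP ", f, ": ", paste(rep, collapse = "; ")))
      next
    }
    if (autoTag && !length(axonTips(g)))
      g <- suppressWarnings(tagAxons(g, autoTag = TRUE))
    log <- c(log, paste0("OK ", f, " (", nNodes(g), " nodes)"))
    summaries[[i]] <- neuronSummary(g)
    if ("distributions" %in% analyses) {
      p <- suppressWarnings(somaPaths(g))
      ang <- branchAngles(g)
      si <- symmetryIndices(g)
      dists[[i]] <- rbind(
        data.frame(label = g@label, metric = "pathLength",
                   value = p$pathLength),
        data.frame(label = g@label, metric = "tortuosity",
                   value = p$tortuosity),
        data.frame(label = g@label, metric = "branchAngle",
                   value = ang$angle),
        data.frame(label = g@label, metric = "symmetryIndex",
                   value = si$si))
    }
    if ("subtrees" %in% analyses && length(axonTips(g)))
      subResults[[g@label]] <- tryCatch(
        fieldReport(g, nIterations = scrambles, seed = seed),
        error = function(e) {
          log <<- c(log, paste0("subtrees failed for ", f, ": ",
                                conditionMessage(e)))
          NULL
        })
    if ("mst" %in% analyses)
      mstResults[[g@label]] <- tryCatch({
        sw <- bfSweep(g, seed = seed)
        compareDistributions(g, sw)
      }, error = function(e) {
        log <<- c(log, paste0("mst failed for ", f, ": ",
                              conditionMessage(e)))
        NULL
      })
  }
  summary <- do.call(rbind, summaries)
  distributions <- if (length(dists)) do.call(rbind, dists) else NULL
  provenance <- list(
    package = "stgmorph",
    version = as.character(utils::packageVersion("stgmorph")),
    rVersion = R.version.string,
    seed = seed,
    config = config[setdiff(names(config), "inputs")],
    inputs = basename(inputs),
    log = log)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(config$outDir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(distributions))
      utils::write.csv(distributions,
                       file.path(config$outDir, "distributions.csv"),
                       row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(config$outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summaries = summary, distributions = distributions,
       subtrees = if (length(subResults)) subResults else NULL,
       mst = if (length(mstResults)) mstResults else NULL,
       skipped = skipped, provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group comparison of a morphometric across cell types
#'
#' Descriptive reporting utility following the study's convention:
#' one-way ANOVA when variance homogeneity holds (Levene's test,
#' p > 0.05), otherwise Kruskal-Wallis; Tukey honest-significant-
#' difference pairwise comparisons with compact letter display in all
#' cases. The homoscedasticity and normality checks that drove the test
#' selection are recorded in the result.
#'
#' @param values numeric samples.
#' @param groups parallel group labels (>= 2 groups with >= 2 samples
#'   each).
#' @param metric name recorded in the result.
#' @param alpha gate level for Levene's test (default 0.05).
#' @return list of class \code{"GroupComparison"}: \code{metric},
#'   \code{test} ("anova" or "kruskal"), \code{statistic}, \code{p},
#'   \code{levene} (p), \code{shapiro} (p, residual normality),
#'   \code{tukey} (pairwise data.frame), \code{letters} (named compact
#'   letter display), \code{groups} (sample sizes).
#' @export
groupCompare <- function(values, groups, metric = "metric",
                         alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L)
    stop("need at least two groups")
  if (any(table(groups) < 2L))
    stop("each group needs at least two samples")
  dat <- data.frame(v = values, g = groups)
  lev <- car::leveneTest(v ~ g, data = dat)
  levP <- lev[["Pr(>F)"]][1]
  fit <- stats::aov(v ~ g, data = dat)
  res <- stats::residuals(fit)
  shapP <- if (length(res) >= 3 && length(res) <= 5000 &&
               stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  if (is.na(levP) || levP > alpha) {
    test <- "anova"
    an <- summary(fit)[[1]]
    statistic <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
  } else {
    test <- "kruskal"
    kw <- stats::kruskal.test(v ~ g, data = dat)
    statistic <- unname(kw$statistic)
    p <- kw$p.value
  }
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  letters <- multcomp::cld(glt, level = alpha)$mcletters$Letters
  tk <- stats::TukeyHSD(fit)$g
  structure(list(metric = metric, test = test, statistic = statistic,
                 p = p, levene = levP, shapiro = shapP,
                 tukey = as.data.frame(tk), letters = letters,
                 groups = table(groups)),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("Group comparison of ", x$metric, " (", x$test, ")\n", sep = "")
  cat("  statistic = ", signif(x$statistic, 5), ", p = ",
      signif(x$p, 4), "\n", sep = "")
  cat("  Levene p = ", signif(x$levene, 4),
      "; residual Shapiro p = ", signif(x$shapiro, 4), "\n", sep = "")
  cat("  Tukey letters:",
      paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  invisible(x)
}
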