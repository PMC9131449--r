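# Declarative pipeline driver: run the configured stages (simulate ->
# esmacs -> ties -> compare -> diststats) against files on disk, writing
# tabular reports plus a reproducibility log.  Two runs with the same
# configuration produce byte-identical outputs.

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

.resolvePath <- function(p, dir) {
  if (is.null(p)) return(NULL)
  if (file.exists(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(dir, p)
}

.writeReport <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the configured analysis pipeline
#'
#' Executes the stages named in `config` in the fixed order `simulate`,
#' `esmacs`, `ties`, `compare`, `diststats`.  `config` is a list or the
#' path to a YAML file with one entry per stage; any stage may be omitted.
#' File paths inside the config are resolved relative to `outdir` (so a
#' `simulate` stage can feed the later ones without absolute paths).  A
#' `run_log.txt` capturing the package version, the top-level seed, every
#' stage's derived seed and the full configuration is always written; the
#' log contains no timestamps, so identical configurations give
#' byte-identical output trees.
#'
#' Stage settings (all optional, with the package defaults):
#' \describe{
#'   \item{simulate}{`assay` (spec list or list of spec lists for
#'     [simulateAssayReplicates()]), `traces` (spec for
#'     [simulateReplicaTraces()], plus `systemId`), `dvdl` (spec with
#'     `coefficientsComplex`, `coefficientsAqueous`, `noiseSd`,
#'     `nSamplesPerWindow`, `nReplicas`, `pairId`), `compounds` (spec for
#'     [simulateCompoundSet()]). Writes `assay.csv`, `traces.tsv`,
#'     `dvdl.tsv`, `compounds.csv`, `calc_estimates.tsv`.}
#'   \item{esmacs}{`traces` (input path), `mode`, `nBoot`. Writes
#'     `esmacs_estimates.tsv`.}
#'   \item{ties}{`dvdl` (input path), `strict`, `nBoot`. Writes
#'     `ties_estimates.tsv`.}
#'   \item{compare}{`compounds`, `estimates` (input paths),
#'     `includeCensored`, `nBoot`. Writes `compare_report.tsv` and
#'     `compare_summary.txt`.}
#'   \item{diststats}{`assay` (input path), `binSize`. Writes
#'     `diststats_moments.tsv` (measurement-statistics layout) and
#'     `diststats_bins.tsv` (sigma-bin layout with the analytic normal
#'     reference row).}
#' }
#'
#' @param config List or path to a YAML file.
#' @param outdir Output directory (created if missing); defaults to
#'   `config$outdir`.
#' @return Invisibly, a named list with each executed stage's in-memory
#'   results and the paths written.
#' @export
runPipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("an output directory is required ('outdir')")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 42L else as.integer(config$seed)
  stageSeeds <- seed + c(simulate = 0L, esmacs = 1L, ties = 2L,
                         compare = 3L, diststats = 4L)
  results <- list()
  paths <- character()

  if (!is.null(config$simulate)) {
    results$simulate <- .stageTry("simulate", {
      cs <- config$simulate
      out <- list()
      if (!is.null(cs$assay)) {
        specs <- if (!is.null(cs$assay$n)) list(cs$assay) else cs$assay
        reps <- lapply(seq_along(specs), function(i) {
          s <- specs[[i]]
          do.call(simulateAssayReplicates, c(
            s[setdiff(names(s), "seed")],
            list(seed = stageSeeds[["simulate"]] + i)))
        })
        paths <<- c(paths, writeAssayTable(reps, file.path(outdir, "assay.csv")))
        out$assay <- reps
      }
      if (!is.null(cs$traces)) {
        s <- cs$traces
        sysId <- if (is.null(s$systemId)) "system" else s$systemId
        s$systemId <- NULL
        if (!is.null(s$meanG)) s$meanG <- unlist(s$meanG)
        tr <- do.call(simulateReplicaTraces, c(
          s[setdiff(names(s), "seed")],
          list(seed = stageSeeds[["simulate"]] + 100L)))
        paths <<- c(paths, writeEnergyTraces(tr$ensembles,
                                             file.path(outdir, "traces.tsv"),
                                             systemId = sysId))
        out$traces <- tr
      }
      if (!is.null(cs$dvdl)) {
        s <- cs$dvdl
        pid <- if (is.null(s$pairId)) "A->B" else s$pairId
        common <- s[intersect(names(s), c("noiseSd", "nSamplesPerWindow",
                                          "nReplicas"))]
        legs <- list(
          do.call(simulateLambdaSamples, c(
            list(coefficients = unlist(s$coefficientsComplex), leg = "complex",
                 pairId = pid, seed = stageSeeds[["simulate"]] + 200L),
            common)),
          do.call(simulateLambdaSamples, c(
            list(coefficients = unlist(s$coefficientsAqueous), leg = "aqueous",
                 pairId = pid, seed = stageSeeds[["simulate"]] + 201L),
            common)))
        paths <<- c(paths, writeDvdl(legs, file.path(outdir, "dvdl.tsv")))
        out$dvdl <- legs
      }
      if (!is.null(cs$compounds)) {
        s <- cs$compounds
        if (!is.null(s$dgRange)) s$dgRange <- unlist(s$dgRange)
        df <- do.call(simulateCompoundSet, c(
          s[setdiff(names(s), "seed")],
          list(seed = stageSeeds[["simulate"]] + 300L)))
        comp <- data.frame(compound_id = df$compound_id,
                           pIC50_mean = dgToPic50(df$dg_exp),
                           net_charge = df$net_charge,
                           censored = 0L, stringsAsFactors = FALSE)
        paths <<- c(paths,
                    writeCompoundTable(comp, file.path(outdir, "compounds.csv")),
                    .writeReport(data.frame(compound_id = df$compound_id,
                                            value = df$dg_calc),
                                 file.path(outdir, "calc_estimates.tsv")))
        out$compounds <- df
      }
      out
    })
  }

  if (!is.null(config$esmacs)) {
    results$esmacs <- .stageTry("esmacs", {
      cs <- config$esmacs
      tracesPath <- .resolvePath(if (is.null(cs$traces)) "traces.tsv"
                                 else cs$traces, outdir)
      systems <- readEnergyTraces(tracesPath, strict = isTRUE(cs$strict))
      nBoot <- if (is.null(cs$nBoot)) 1000L else cs$nBoot
      mode <- if (is.null(cs$mode)) "one_trajectory" else cs$mode
      est <- lapply(systems, function(rl) {
        if (!all(.ROLES %in% names(rl)))
          stop("system lacks complex/protein/ligand roles")
        esmacsEstimate(rl$complex, rl$protein, rl$ligand, mode = mode,
                       nBoot = nBoot, seed = stageSeeds[["esmacs"]])
      })
      df <- data.frame(system_id = names(est),
                       value = vapply(est, feValue, numeric(1L)),
                       se = vapply(est, feSE, numeric(1L)),
                       n_replicas = vapply(est, nReplicas, integer(1L)))
      paths <<- c(paths, .writeReport(df, file.path(outdir, "esmacs_estimates.tsv")))
      est
    })
  }

  if (!is.null(config$ties)) {
    results$ties <- .stageTry("ties", {
      cs <- config$ties
      dvdlPath <- .resolvePath(if (is.null(cs$dvdl)) "dvdl.tsv" else cs$dvdl,
                               outdir)
      pairs <- readDvdl(dvdlPath, strict = isTRUE(cs$strict))
      nBoot <- if (is.null(cs$nBoot)) 1000L else cs$nBoot
      est <- lapply(pairs, function(legs) {
        if (!all(c("complex", "aqueous") %in% names(legs)))
          stop("pair lacks a complex or aqueous leg")
        tiesEstimate(legs$complex, legs$aqueous, nBoot = nBoot,
                     seed = stageSeeds[["ties"]], strict = isTRUE(cs$strict))
      })
      df <- data.frame(pair_id = names(est),
                       ddg = vapply(est, ddG, numeric(1L)),
                       se = vapply(est, feSE, numeric(1L)),
                       dg_complex = vapply(est, function(e) feValue(e@dgComplex),
                                           numeric(1L)),
                       dg_aqueous = vapply(est, function(e) feValue(e@dgAqueous),
                                           numeric(1L)))
      paths <<- c(paths, .writeReport(df, file.path(outdir, "ties_estimates.tsv")))
      est
    })
  }

  if (!is.null(config$compare)) {
    results$compare <- .stageTry("compare", {
      cs <- config$compare
      records <- readCompoundTable(.resolvePath(
        if (is.null(cs$compounds)) "compounds.csv" else cs$compounds, outdir))
      estPath <- .resolvePath(
        if (is.null(cs$estimates)) "calc_estimates.tsv" else cs$estimates,
        outdir)
      estimates <- utils::read.delim(estPath, stringsAsFactors = FALSE)
      records$pIC50 <- records$pIC50_mean
      nBoot <- if (is.null(cs$nBoot)) 10000L else cs$nBoot
      rep <- comparisonReport(records, estimates,
                              includeCensored = isTRUE(cs$includeCensored),
                              nBoot = nBoot, seed = stageSeeds[["compare"]])
      df <- data.frame(
        statistic = c("pearson", "pearson_ci_lo", "pearson_ci_hi",
                      "spearman", "spearman_ci_lo", "spearman_ci_hi",
                      "mue", "mse", "n_pairs", "slope", "intercept"),
        value = c(rep@pearson, rep@pearsonCI, rep@spearman, rep@spearmanCI,
                  rep@mue, rep@mse, rep@nPairs, rep@slope, rep@intercept))
      paths <<- c(paths, .writeReport(df, file.path(outdir, "compare_report.tsv")))
      writeLines(utils::capture.output(show(rep)),
                 file.path(outdir, "compare_summary.txt"))
      paths <<- c(paths, file.path(outdir, "compare_summary.txt"))
      rep
    })
  }

  if (!is.null(config$diststats)) {
    results$diststats <- .stageTry("diststats", {
      cs <- config$diststats
      reps <- readAssayTable(.resolvePath(
        if (is.null(cs$assay)) "assay.csv" else cs$assay, outdir))
      sums <- lapply(reps, summarizeDistribution)
      moments <- data.frame(
        compound = names(sums),
        n = vapply(sums, function(s) s@n, integer(1L)),
        average = round(vapply(sums, function(s) s@mean, numeric(1L)), 2L),
        SD = round(vapply(sums, function(s) s@sd, numeric(1L)), 2L),
        skewness = round(vapply(sums, function(s) s@skewness, numeric(1L)), 2L),
        kurtosis = round(vapply(sums, function(s) s@excessKurtosis,
                                numeric(1L)), 2L))
      drift <- lapply(reps, function(a) {
        v <- assayValues(a)
        if (length(v) >= 10L)
          driftTest(v, nPerm = 2000L, seed = stageSeeds[["diststats"]])
        else list(slope = NA_real_, p = NA_real_, driftFlag = NA)
      })
      moments$drift_slope <- signif(vapply(drift, function(d) d$slope,
                                           numeric(1L)), 3L)
      moments$drift_p <- signif(vapply(drift, function(d) d$p, numeric(1L)), 3L)
      binRows <- t(vapply(sums, function(s) round(s@binFractions, 1L),
                          numeric(6L)))
      bins <- data.frame(compound = c(names(sums), "normal"),
                         rbind(binRows, round(normalReferenceBins(), 1L)))
      names(bins)[-1L] <- c("lt_m2s", "m2s_m1s", "m1s_0", "0_p1s", "p1s_p2s",
                            "gt_p2s")
      paths <<- c(paths,
                  .writeReport(moments, file.path(outdir, "diststats_moments.tsv")),
                  .writeReport(bins, file.path(outdir, "diststats_bins.tsv")))
      list(summaries = sums, drift = drift)
    })
  }

  log <- c(
    sprintf("ensembleFE %s", as.character(utils::packageVersion("ensembleFE"))),
    sprintf("seed: %d", seed),
    sprintf("stage seeds: %s",
            paste(sprintf("%s=%d", names(stageSeeds), stageSeeds),
                  collapse = ", ")),
    "config:",
    strsplit(yaml::as.yaml(config), "\n")[[1L]])
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(c(results, list(paths = c(paths, file.path(outdir, "run_log.txt")))))
}
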