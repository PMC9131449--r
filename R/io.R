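# Readers and writers for the package's tabular dialects.
#
# The formats are deliberately engine-agnostic: MD packages emit per-frame
# energies and dV/dlambda samples in many dialects, so the analysis reads a
# documented minimal intermediate instead of any engine's native output.
# All energies are kcal/mol.  Writers emit exactly what the readers accept
# (round-trip property), tab-separated with a header; '#' comment lines are
# allowed.

# Read a TSV keeping track of the source line number of every data row, so
# validation errors can name the offending line.
.readTsv <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  if (sum(keep) < 2L) stop("no data rows in ", path)
  df <- utils::read.table(text = raw[keep], sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "lineNumbers") <- which(keep)[-1L]
  df
}

.requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
}

# ---------------------------------------------------------------------------
# Energy traces
# ---------------------------------------------------------------------------

#' Read per-frame energy traces
#'
#' Reads the energy-trace dialect (tab-separated, header `system_id,
#' replica_id, frame, role, e_mm, g_polar, g_nonpolar, g_total`, `#`
#' comments allowed) and returns, per system, one
#' [EnergyEnsemble-class] per component role.  Rows violating the
#' component-sum invariant (`g_total = e_mm + g_polar + g_nonpolar` within
#' 1e-6) are reported with their line numbers.  Component columns may be
#' `NA` throughout, in which case only totals are stored.
#'
#' @param path File path.
#' @param strict If `TRUE`, replicas of one role with differing frame
#'   counts are an error; otherwise all replicas are truncated to the
#'   shortest with a warning.
#' @return Named list (by system) of named lists (by role) of
#'   `EnergyEnsemble` objects.
#' @export
readEnergyTraces <- function(path, strict = FALSE) {
  cols <- c("system_id", "replica_id", "frame", "role",
            "e_mm", "g_polar", "g_nonpolar", "g_total")
  df <- .readTsv(path)
  .requireColumns(df, cols, path)
  lineNo <- attr(df, "lineNumbers")
  if (!all(df$role %in% .ROLES))
    stop(path, ": role must be one of ", paste(.ROLES, collapse = ", "))
  if (!all(is.finite(df$g_total)))
    stop(path, ": non-finite g_total values")
  hasComp <- stats::complete.cases(df[, c("e_mm", "g_polar", "g_nonpolar")])
  if (any(hasComp)) {
    bad <- hasComp &
      abs(df$e_mm + df$g_polar + df$g_nonpolar - df$g_total) > 1e-6
    if (any(bad))
      stop(sprintf(
        "%s: g_total differs from e_mm + g_polar + g_nonpolar by more than 1e-6 at line(s) %s",
        path, paste(lineNo[bad], collapse = ", ")))
  }
  key <- paste(df$system_id, df$role, df$replica_id, df$frame)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("%s: duplicate (replica, frame, role) record at line %d",
                 path, lineNo[d]))
  }
  out <- list()
  for (sys in unique(df$system_id)) {
    dsys <- df[df$system_id == sys, , drop = FALSE]
    roles <- list()
    for (role in unique(dsys$role)) {
      d <- dsys[dsys$role == role, , drop = FALSE]
      reps <- sort(unique(d$replica_id))
      counts <- table(d$replica_id)
      if (length(unique(counts)) > 1L) {
        if (strict)
          stop(sprintf("%s: inconsistent frame counts across replicas for %s/%s (strict mode)",
                       path, sys, role))
        warning(sprintf("%s/%s: truncating replicas to the shortest frame series",
                        sys, role))
      }
      nf <- min(counts)
      grab <- function(col) {
        m <- vapply(reps, function(r) {
          dr <- d[d$replica_id == r, , drop = FALSE]
          dr <- dr[order(dr$frame), , drop = FALSE]
          dr[[col]][seq_len(nf)]
        }, numeric(nf))
        m <- matrix(m, nrow = nf)
        colnames(m) <- reps
        m
      }
      comp <- list()
      dcomp <- stats::complete.cases(d[, c("e_mm", "g_polar", "g_nonpolar")])
      if (all(dcomp))
        comp <- list(e_mm = grab("e_mm"), g_polar = grab("g_polar"),
                     g_nonpolar = grab("g_nonpolar"))
      roles[[role]] <- EnergyEnsemble(grab("g_total"), role,
                                      components = comp)
    }
    out[[sys]] <- roles
  }
  out
}

#' Write per-frame energy traces
#'
#' @param ensembles Named list (by role) of [EnergyEnsemble-class]
#'   objects, or a named list of such lists (by system id).
#' @param path Output file path.
#' @param systemId System label used when `ensembles` is a single system.
#' @return `path`, invisibly.
#' @export
writeEnergyTraces <- function(ensembles, path, systemId = "system") {
  if (length(ensembles) && is(ensembles[[1L]], "EnergyEnsemble"))
    ensembles <- stats::setNames(list(ensembles), systemId)
  rows <- list()
  for (sys in names(ensembles)) for (role in names(ensembles[[sys]])) {
    e <- ensembles[[sys]][[role]]
    fr <- frameEnergies(e)
    comp <- e@components
    for (r in seq_len(ncol(fr))) {
      g <- fr[, r]
      rows[[length(rows) + 1L]] <- data.frame(
        system_id = sys, replica_id = colnames(fr)[r],
        frame = seq_along(g), role = role,
        e_mm = if (length(comp)) comp$e_mm[, r] else NA_real_,
        g_polar = if (length(comp)) comp$g_polar[, r] else NA_real_,
        g_nonpolar = if (length(comp)) comp$g_nonpolar[, r] else NA_real_,
        g_total = g, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# dV/dlambda tables
# ---------------------------------------------------------------------------

#' Read dV/dlambda sample tables
#'
#' Reads the dialect `pair_id, leg, replica_id, lambda, sample_index,
#' dvdl` (tab-separated) and returns one [LambdaLeg-class] per
#' `(pair_id, leg)` combination.
#'
#' @param path File path.
#' @param strict If `TRUE`, replicas whose lambda schedules disagree are
#'   an error; otherwise windows hold whichever replicas sampled them.
#' @return Named list (by pair id) of named lists (by leg).
#' @export
readDvdl <- function(path, strict = FALSE) {
  cols <- c("pair_id", "leg", "replica_id", "lambda", "sample_index", "dvdl")
  df <- .readTsv(path)
  .requireColumns(df, cols, path)
  lineNo <- attr(df, "lineNumbers")
  bad <- !is.finite(df$lambda) | df$lambda < 0 | df$lambda > 1
  if (any(bad))
    stop(sprintf("%s: lambda outside [0, 1] at line(s) %s", path,
                 paste(lineNo[bad], collapse = ", ")))
  if (!all(df$leg %in% .LEGS))
    stop(path, ": leg must be 'aqueous' or 'complex'")
  out <- list()
  for (pid in unique(df$pair_id)) {
    legs <- list()
    for (leg in unique(df$leg[df$pair_id == pid])) {
      d <- df[df$pair_id == pid & df$leg == leg, , drop = FALSE]
      lams <- sort(unique(d$lambda))
      if (strict) {
        perRep <- tapply(d$lambda, d$replica_id,
                         function(l) paste(sort(unique(l)), collapse = ","))
        if (length(unique(perRep)) > 1L)
          stop(sprintf("%s: lambda schedule differs across replicas for %s/%s (strict mode)",
                       path, pid, leg))
      }
      samples <- lapply(lams, function(l) {
        dw <- d[d$lambda == l, , drop = FALSE]
        reps <- sort(unique(dw$replica_id))
        ns <- table(dw$replica_id)
        if (length(unique(ns)) > 1L)
          stop(sprintf("%s: unequal sample counts within window lambda=%g of %s/%s",
                       path, l, pid, leg))
        m <- vapply(reps, function(r) {
          dr <- dw[dw$replica_id == r, , drop = FALSE]
          dr$dvdl[order(dr$sample_index)]
        }, numeric(ns[1L]))
        m <- matrix(m, nrow = ns[1L])
        colnames(m) <- reps
        m
      })
      legs[[leg]] <- LambdaLeg(lams, samples, leg = leg, pairId = pid)
    }
    out[[pid]] <- legs
  }
  out
}

#' Write dV/dlambda sample tables
#'
#' @param legs A [LambdaLeg-class] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeDvdl <- function(legs, path) {
  if (is(legs, "LambdaLeg")) legs <- list(legs)
  rows <- list()
  for (leg in legs) {
    lams <- lambdaSchedule(leg)
    ws <- windowSamples(leg)
    for (w in seq_along(lams)) {
      m <- ws[[w]]
      for (r in seq_len(ncol(m)))
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = pairId(leg), leg = legLabel(leg),
          replica_id = colnames(m)[r], lambda = lams[w],
          sample_index = seq_len(nrow(m)), dvdl = m[, r],
          stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Assay replicate and compound tables
# ---------------------------------------------------------------------------

#' Read an assay replicate table
#'
#' CSV with columns `compound_id, pIC50` and optional `date` (ISO-8601).
#'
#' @param path File path.
#' @return Named list of [AssayReplicates-class], one per compound, in
#'   file order.
#' @export
readAssayTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .requireColumns(df, c("compound_id", "pIC50"), path)
  if (!all(is.finite(df$pIC50))) stop(path, ": non-finite pIC50 values")
  out <- list()
  for (cid in unique(df$compound_id)) {
    d <- df[df$compound_id == cid, , drop = FALSE]
    out[[cid]] <- AssayReplicates(
      d$pIC50, compoundId = cid,
      timestamps = if ("date" %in% names(d)) as.character(d$date)
                   else character())
  }
  out
}

#' Write an assay replicate table
#'
#' @param replicates An [AssayReplicates-class] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAssayTable <- function(replicates, path) {
  if (is(replicates, "AssayReplicates")) replicates <- list(replicates)
  rows <- lapply(replicates, function(a) {
    d <- data.frame(compound_id = compoundId(a), pIC50 = assayValues(a),
                    stringsAsFactors = FALSE)
    if (length(a@timestamps)) d$date <- a@timestamps
    d
  })
  hasDate <- any(vapply(rows, function(d) "date" %in% names(d), logical(1L)))
  if (hasDate)
    rows <- lapply(rows, function(d) {
      if (!("date" %in% names(d))) d$date <- NA_character_
      d
    })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a compound summary table
#'
#' CSV with columns `compound_id, pIC50_mean, net_charge, censored`
#' (`censored` is 0/1; a censored entry means the assay reported no
#' activity at the highest tested concentration, so the potency is a
#' bound).
#'
#' @param path File path.
#' @return Data frame.
#' @export
readCompoundTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .requireColumns(df, c("compound_id", "pIC50_mean", "net_charge", "censored"),
                  path)
  if (!all(is.finite(df$pIC50_mean))) stop(path, ": non-finite pIC50_mean")
  if (!all(df$censored %in% c(0L, 1L)))
    stop(path, ": censored must be 0 or 1")
  df$censored <- as.logical(df$censored)
  df
}

#' @rdname readCompoundTable
#' @param df Data frame with the four columns above.
#' @export
writeCompoundTable <- function(df, path) {
  .requireColumns(df, c("compound_id", "pIC50_mean", "net_charge", "censored"),
                  "compound table")
  df$censored <- as.integer(df$censored)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
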