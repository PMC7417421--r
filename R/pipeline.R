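#' Run the full per-subject analysis pipeline
#'
#' Orchestrates, for a list of subjects: reading the AA matrix, optional
#' pre-filtering, dominant-frequency estimation, recurrence indices, SVAAP,
#' and an optional logistic association of the normalised indices with a
#' binary outcome. Per-subject failures are caught, recorded and skipped so
#' one bad recording does not abort a cohort run. A JSON manifest
#' (parameters, seed, file checksums, package version) sufficient to
#' reproduce the run is written next to the reports.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{subjects}{data.frame or list with `id` and `path` per subject.}
#'     \item{fs}{sampling rate in Hz (required).}
#'     \item{preprocess}{logical; apply [preprocessAA()] first (default
#'       FALSE, inputs assumed AA-only and pre-filtered).}
#'     \item{M, ltrBand}{recurrence window (default 500) and LTR lag band
#'       (default c(150, 450)).}
#'     \item{fAF}{numeric dominant frequency, or `"estimate"` (default) for
#'       per-subject Welch estimation.}
#'     \item{longWindow}{long SVAAP segment in seconds (default 5).}
#'     \item{outcomes}{optional named binary vector (names = subject ids).}
#'     \item{outDir}{output directory (default `"."`).}
#'     \item{seed}{integer seed recorded in the manifest (default 1).}
#'   }
#'
#' @return Invisibly, a list with `results` (per-subject data.frame),
#'   `association` (or NULL), `failures`, and `manifest`.
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    fs <- config$fs
    if (is.null(fs)) stop("config must provide 'fs'")
    M <- if (is.null(config$M)) 500L else as.integer(config$M)
    band <- if (is.null(config$ltrBand)) c(150L, 450L)
            else as.integer(config$ltrBand)
    longWindow <- if (is.null(config$longWindow)) 5 else config$longWindow
    outDir <- if (is.null(config$outDir)) "." else config$outDir
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    subjects <- as.data.frame(config$subjects)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)

    rows <- list()
    failures <- list()
    for (k in seq_len(nrow(subjects))) {
        id <- as.character(subjects$id[k])
        res <- tryCatch({
            x <- readAASignals(subjects$path[k], fs = fs)
            if (isTRUE(config$preprocess)) x <- preprocessAA(x)
            fAF <- if (is.null(config$fAF) ||
                       identical(config$fAF, "estimate"))
                dominantFrequency(x)@fAF else as.numeric(config$fAF)
            idx <- subjectIndices(x, M = M, lo = band[1L], hi = band[2L])
            sv <- svaap(x, fAF = fAF, longWindow = longWindow)
            cbind(indicesToDataFrame(idx, subject = id),
                  f_af = fAF, s_svaap = sv@sSvaap, l_svaap = sv@lSvaap)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            failures[[id]] <- conditionMessage(res)
            message("subject ", id, " failed: ", conditionMessage(res))
        } else rows[[id]] <- res
    }
    emptyCols <- c("subject", "p1_abs", "t_p1", "p2", "t_p2", "ltr",
                   "norm_p1", "norm_p2", "n_blocks", "n_degenerate",
                   "f_af", "s_svaap", "l_svaap")
    results <- if (length(rows)) do.call(rbind, rows)
              else stats::setNames(
                  as.data.frame(rep(list(numeric(0)), length(emptyCols))),
                  emptyCols)
    rownames(results) <- NULL

    association <- NULL
    if (!is.null(config$outcomes) && nrow(results)) {
        oc <- config$outcomes
        y <- as.integer(oc[match(results$subject, names(oc))])
        keep <- !is.na(y)
        if (sum(keep) >= 4L)
            association <- list(
                norm_p1 = univariateAssociation(results$norm_p1[keep],
                                                y[keep]),
                norm_p2 = univariateAssociation(results$norm_p2[keep],
                                                y[keep]))
    }

    data.table::fwrite(results, file.path(outDir, "subjects.csv"))
    jsonlite::write_json(results, file.path(outDir, "subjects.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest <- list(
        package = "aadyn",
        version = as.character(utils::packageVersion("aadyn")),
        fs = fs, M = M, ltrBand = band, longWindow = longWindow,
        fAF = if (is.null(config$fAF)) "estimate" else config$fAF,
        preprocess = isTRUE(config$preprocess), seed = seed,
        files = as.list(stats::setNames(
            unname(tools::md5sum(as.character(subjects$path))),
            as.character(subjects$id))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(results = results, association = association,
                   failures = failures, manifest = manifest))
}
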