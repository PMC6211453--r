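#' Serialize a fitted model to JSON
#'
#' Writes a versioned JSON document with the GLM coefficients, library
#' sizes, dispersion, event-mixture parameters, transition parameters
#' and the EM log-evidence trace.
#'
#' @param model A [ClipModel-class].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeModelJson <- function(model, path) {
    glm <- model@glm
    doc <- list(
        format = "clipHMM-model",
        version = 1L,
        glm = list(
            beta0 = glm@beta0,
            beta_gene = as.list(glm@beta_gene),
            beta_enrich = glm@beta_enrich,
            libsize = as.list(glm@libsize),
            dispersion = glm@dispersion,
            converged = glm@converged),
        dmm = lapply(list(peak = model@dmm_peak,
                background = model@dmm_background), function(m) list(
            weights = m@weights,
            alphas = apply(m@alphas, 1L, identity, simplify = FALSE))),
        transitions = list(w0 = model@transitions@w0,
            w1 = model@transitions@w1),
        logevidence = model@logevidence,
        n_iter = model@n_iter)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Run the full peak-calling pipeline
#'
#' Loads alignments and annotation, builds per-gene tensors with all
#' read/position filters, fits the model by EM and calls
#' Bonferroni-filtered peaks.  Writes a BED6+ peak file, a model JSON
#' and a plain-text run report into \code{out_dir}.
#'
#' @param clip,background Named character vectors of SAM/BAM paths (or
#'   named lists of [ReadSet-class]); at least one CLIP library is
#'   required, background libraries are optional.
#' @param annotation GTF/GFF path or GRanges of gene spans.
#' @param out_dir Output directory.
#' @param mirna Optional miRNA annotation (BED/GTF path or GRanges);
#'   positions in genes overlapping these are masked entirely.
#' @param peak_penalty Decode-time log-penalty on the peak state
#'   (default 0; -5 recommended for eCLIP peak cores).
#' @param max_mismatches,snp_min_reads,snp_min_frac Read and SNP
#'   filter thresholds.
#' @param k_components,min_iter,max_iter,seed EM settings, see
#'   [emFit()].
#' @param alpha Bonferroni-corrected p-value threshold (default 0.05).
#' @param verbose Print progress.
#' @return Invisibly, a list with \code{peaks}, \code{model},
#'   \code{tensors} and output \code{paths}.
#' @export
runPipeline <- function(clip, background = NULL, annotation, out_dir,
                        mirna = NULL, peak_penalty = 0,
                        max_mismatches = 2L, snp_min_reads = 20L,
                        snp_min_frac = 0.2, k_components = 10L,
                        min_iter = 5L, max_iter = 10L, seed = 1L,
                        alpha = 0.05, verbose = FALSE) {
    if (length(clip) < 1L)
        stop("at least one CLIP library is required")
    alignments <- c(as.list(clip), as.list(background))
    if (is.null(names(alignments)) || any(names(alignments) == ""))
        names(alignments) <- c(
            sprintf("clip%d", seq_along(clip)),
            if (length(background))
                sprintf("bg%d", seq_along(background)))
    roles <- c(rep("CLIP", length(clip)),
        rep("background", length(background)))
    tensors <- readClipData(alignments, roles, annotation,
        mirna = mirna, max_mismatches = max_mismatches,
        snp_min_reads = snp_min_reads, snp_min_frac = snp_min_frac)
    empty <- vapply(tensors, function(t) sum(t@coverage) == 0, TRUE)
    if (all(empty)) stop("no reads overlap the annotation")
    model <- emFit(tensors, k_components = k_components,
        min_iter = min_iter, max_iter = max_iter, seed = seed,
        verbose = verbose)
    peaks <- callPeaks(tensors, model, peak_penalty = peak_penalty,
        alpha = alpha)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
        peaks = file.path(out_dir, "peaks.bed"),
        model = file.path(out_dir, "model.json"),
        log = file.path(out_dir, "run_report.txt"))
    exportPeaks(peaks, paths$peaks)
    writeModelJson(model, paths$model)
    glm <- model@glm
    writeLines(c(
        "clipHMM run report",
        sprintf("libraries: %s", paste(sprintf("%s(%s)",
            names(alignments), roles), collapse = ", ")),
        sprintf("genes: %d", length(tensors)),
        sprintf("library log sizes: %s", paste(sprintf("%s=%.3f",
            names(glm@libsize), glm@libsize), collapse = ", ")),
        sprintf("dispersion c: %.5f", glm@dispersion),
        sprintf("enrichment beta: %.4f", glm@beta_enrich),
        sprintf("EM iterations: %d", model@n_iter),
        sprintf("log-evidence trace: %s",
            paste(sprintf("%.2f", model@logevidence),
                collapse = " ")),
        sprintf("settings: peak_penalty=%g max_mismatches=%d %s",
            peak_penalty, max_mismatches,
            sprintf("snp=%d/%.2f K=%d iter=%d-%d alpha=%g seed=%d",
                snp_min_reads, snp_min_frac, k_components, min_iter,
                max_iter, alpha, seed)),
        sprintf("candidate peaks passing Bonferroni %.2f: %d", alpha,
            length(peaks))), paths$log)
    invisible(list(peaks = peaks, model = model, tensors = tensors,
        paths = paths))
}
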