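#' Log-likelihood-ratio score of a peak
#'
#' Sum over the peak's positions of the peak-state emission
#' log-probability minus the best non-peak emission log-probability.
#'
#' @param log_emissions Positions x 4 emission matrix for the gene.
#' @param positions Local positions of the peak.
#' @return Numeric score.
#' @export
scorePeak <- function(log_emissions, positions) {
    e <- log_emissions[positions, , drop = FALSE]
    sum(e[, 1L] - apply(e[, 2:4, drop = FALSE], 1L, max))
}

#' Negative-binomial tail p-value for a peak
#'
#' The expected mean and variance of CLIP coverage under the
#' expression-matched non-enriched state (B2) are summed over the
#' peak's positions and CLIP libraries; the p-value is the upper-tail
#' probability of the observed summed CLIP coverage under a negative
#' binomial moment-matched to that mean and variance (Poisson when the
#' summed variance does not exceed the mean).
#'
#' @param tensor The gene's [SiteTensor-class].
#' @param glm The fitted [CoverageGLM-class].
#' @param positions Local positions of the peak.
#' @return p-value in (0, 1].
#' @export
peakPValue <- function(tensor, glm, positions) {
    clip <- which(tensor@lib_roles == "CLIP")
    mu_lib <- vapply(clip, function(w)
        exp(min(stateLogMean(glm, tensor@gene_id,
            tensor@lib_names[w], "CLIP", "B2"), 30)), numeric(1))
    n <- length(positions)
    mu_tot <- n * sum(mu_lib)
    var_tot <- mu_tot + glm@dispersion * n * sum(mu_lib^2)
    obs <- sum(tensor@coverage[positions, clip])
    if (var_tot <= mu_tot) {
        p <- ppois(obs - 1, lambda = mu_tot, lower.tail = FALSE)
    } else {
        size <- mu_tot^2 / (var_tot - mu_tot)
        p <- pnbinom(obs - 1, size = size, mu = mu_tot,
            lower.tail = FALSE)
    }
    max(min(p, 1), .Machine$double.xmin)
}

#' Call peaks from a fitted model
#'
#' Decodes every gene with the Viterbi algorithm and turns maximal
#' runs of the peak state into candidate peaks.  Each peak carries a
#' summit (the position of maximal diagnostic-event log-odds), a
#' log-likelihood-ratio score, an NB tail p-value and its Bonferroni
#' correction over all candidates; peaks with adjusted p-value above
#' \code{alpha} are dropped.
#'
#' @param tensors Named list of [SiteTensor-class].
#' @param model A fitted [ClipModel-class].
#' @param peak_penalty Decode-time additive log-penalty on the peak
#'   state (default 0; use e.g. -5 to restrict eCLIP peaks to their
#'   high-confidence cores).
#' @param alpha Bonferroni-corrected p-value threshold (default 0.05).
#' @return A [GenomicRanges::GRanges] of peaks with metadata columns
#'   \code{gene_id}, \code{summit} (genomic position),
#'   \code{site_score}, \code{p_value}, \code{p_adj}.
#' @export
callPeaks <- function(tensors, model, peak_penalty = 0, alpha = 0.05) {
    glm_adj <- adjustBetaForEmission(model@glm)
    res <- list()
    for (g in seq_along(tensors)) {
        t <- tensors[[g]]
        cache <- list(clip = .eventCache(t, "CLIP"),
            bg = .eventCache(t, "background"))
        em <- emissionMatrix(t, glm_adj, model@dmm_peak,
            model@dmm_background, cache = cache)
        cov <- rowSums(t@coverage)
        path <- viterbiPath(em, cov, model@transitions, peak_penalty)
        r <- rle(path == 1L)
        if (!any(r$values)) next
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        lo <- .eventLogOdds(t, model@dmm_peak, model@dmm_background,
            cache = cache$clip)
        for (k in which(r$values)) {
            pos <- starts[k]:ends[k]
            summit_local <- pos[which.max(lo[pos])]
            res[[length(res) + 1L]] <- data.frame(
                chrom = t@chrom,
                start = t@start + starts[k] - 1L,
                end = t@start + ends[k] - 1L,
                strand = t@strand,
                gene_id = t@gene_id,
                summit = t@start + summit_local - 1L,
                site_score = scorePeak(em, pos),
                p_value = peakPValue(t, model@glm, pos))
        }
    }
    if (!length(res)) {
        return(GenomicRanges::GRanges(gene_id = character(),
            summit = integer(), site_score = numeric(),
            p_value = numeric(), p_adj = numeric()))
    }
    df <- do.call(rbind, res)
    df$p_adj <- pmin(df$p_value * nrow(df), 1)
    df <- df[df$p_adj <= alpha, , drop = FALSE]
    GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start, end = df$end),
        strand = df$strand,
        gene_id = df$gene_id,
        summit = df$summit,
        site_score = df$site_score,
        p_value = df$p_value,
        p_adj = df$p_adj)
}

#' Random placement control for peak scores
#'
#' Re-places each peak uniformly at random within its gene (same
#' width, same strand) and returns the scorer's values on the shuffled
#' intervals, quantifying the score distribution expected by chance.
#'
#' @param peaks [GenomicRanges::GRanges] of peaks with a
#'   \code{gene_id} column.
#' @param genes [GenomicRanges::GRanges] of gene spans with a
#'   \code{gene_id} column.
#' @param scorer Function mapping a GRanges of intervals to a numeric
#'   score vector.
#' @param seed RNG seed.
#' @return Numeric vector of control scores.
#' @export
shuffleControl <- function(peaks, genes, scorer, seed = 1L) {
    set.seed(seed)
    gidx <- match(peaks$gene_id, genes$gene_id)
    widths <- GenomicRanges::width(peaks)
    gw <- GenomicRanges::width(genes)[gidx]
    ok <- widths <= gw
    if (any(!ok))
        warning(sum(!ok), " peaks wider than their gene were skipped")
    room <- gw[ok] - widths[ok]
    new_start <- GenomicRanges::start(genes)[gidx][ok] +
        floor(runif(sum(ok)) * (room + 1))
    shuffled <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(peaks)[ok],
        ranges = IRanges::IRanges(start = new_start,
            width = widths[ok]),
        strand = GenomicRanges::strand(peaks)[ok])
    scorer(shuffled)
}

#' Write peaks as BED6+
#'
#' Columns: chrom, start (0-based), end, name (gene:index), score
#' (site score), strand, then summit offset within the peak, p-value
#' and Bonferroni-adjusted p-value.
#'
#' @param peaks GRanges from [callPeaks()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
exportPeaks <- function(peaks, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(peaks)),
        start = GenomicRanges::start(peaks) - 1L,
        end = GenomicRanges::end(peaks),
        name = paste0(peaks$gene_id, ":", seq_along(peaks)),
        score = round(peaks$site_score, 4),
        strand = as.character(GenomicRanges::strand(peaks)),
        summit_offset = peaks$summit - GenomicRanges::start(peaks),
        p_value = signif(peaks$p_value, 6),
        p_adj = signif(peaks$p_adj, 6))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    invisible(path)
}
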