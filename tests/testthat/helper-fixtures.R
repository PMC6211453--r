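# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# a ReadSet from a compact spec: one row per read
make_reads <- function(df, mismatches = NULL, deletions = NULL) {
    ReadSet(chrom = df$chrom, start = df$start, end = df$end,
        strand = df$strand, read_length = df$read_length,
        mismatches = mismatches, deletions = deletions)
}

# a SiteTensor built directly from matrices
make_tensor <- function(coverage, events = NULL, roles,
                        gene_id = "g1", chrom = "chr1", strand = "+",
                        start = 1L, snp_mask = NULL) {
    n <- nrow(coverage)
    if (is.null(events))
        events <- data.frame(pos = integer(), lib = integer(),
            cat = integer(), count = integer())
    if (is.null(snp_mask)) snp_mask <- rep(FALSE, n)
    methods::new("SiteTensor", gene_id = gene_id, chrom = chrom,
        strand = strand, start = as.integer(start), n_pos = n,
        coverage = coverage, events = events,
        lib_names = colnames(coverage), lib_roles = roles,
        snp_mask = snp_mask, mirna_mask = rep(FALSE, n),
        overlap_mask = rep(FALSE, n))
}

# small end-to-end simulation + fit, shared across test files
small_fit_fixture <- function() {
    if (!is.null(.fixture_env$small)) return(.fixture_env$small)
    cfg <- simConfig(n_genes = 25L, n_reads = 2.5e4, seed = 7L)
    sim <- simulateClipData(cfg)
    tensors <- readClipData(sim$readsets, sim$roles, sim$genes)
    model <- emFit(tensors, seed = 1L, min_iter = 3L, max_iter = 6L)
    peaks <- callPeaks(tensors, model)
    .fixture_env$small <- list(sim = sim, tensors = tensors,
        model = model, peaks = peaks)
    .fixture_env$small
}

# the full-scale simulated study: simulator defaults (200 genes, 2
# CLIP + 2 background libraries), one fixed simulation seed, model
# fits from two different seeds
acceptance_fixture <- function() {
    if (!is.null(.fixture_env$acc)) return(.fixture_env$acc)
    cfg <- simConfig(seed = 101L)
    sim <- simulateClipData(cfg)
    tensors <- readClipData(sim$readsets, sim$roles, sim$genes)
    model <- emFit(tensors, seed = 1L)
    peaks <- callPeaks(tensors, model)
    model2 <- emFit(tensors, seed = 2L)
    peaks2 <- callPeaks(tensors, model2)
    .fixture_env$acc <- list(sim = sim, tensors = tensors,
        model = model, peaks = peaks, model2 = model2,
        peaks2 = peaks2)
    .fixture_env$acc
}
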