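#' Default simulation configuration
#'
#' Desk-scale defaults for the CLIP-seq simulator: 200 single-exon
#' genes of ~2 kb, log-normal base expressions exp(N(10, 4)),
#' negative-binomial replicate counts with variance mu + 0.1 mu^2, six
#' replicate libraries (2 background, 2 CLIP, 2 held-out non-specific
#' libraries admixed at 10% into the CLIP libraries), motif-anchored
#' A-to-T conversions in 50% of crosslink-covering CLIP reads and
#' motif-score-dependent read retention.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Min/max gene length in bp.
#' @param expression_log_mean,expression_log_var Parameters of the
#'   log-normal base expression distribution.
#' @param replicate_dispersion Overdispersion c of replicate counts.
#' @param n_clip,n_background Number of CLIP and background libraries.
#' @param read_length Read length in bp.
#' @param n_reads Fragments drawn per library before CLIP filtering.
#' @param pwm 4 x width probability matrix (rows A, C, G, T).
#' @param pwm_threshold Log2-odds match threshold.
#' @param pwm_pseudocount Pseudocount added to PWM probabilities.
#' @param sites_per_gene_mean Mean number of planted motif instances
#'   per gene (1 + Poisson(mean - 1)).
#' @param conversion_rate Fraction of crosslink-covering CLIP reads
#'   receiving the A-to-T conversion.
#' @param background_mix Fraction of held-out non-specific reads
#'   admixed into each CLIP library.
#' @param retention \code{"score-proportional"} keeps a
#'   motif-overlapping read with probability proportional to its
#'   maximal motif score's position within the genome-wide score
#'   range; \code{"literal"} inverts the comparison (retention
#'   decreasing in score).
#' @param seed RNG seed.
#' @return A named list of configuration values.
#' @export
simConfig <- function(n_genes = 200L, gene_length_range = c(1500L,
                          2500L),
                      expression_log_mean = 10,
                      expression_log_var = 4,
                      replicate_dispersion = 0.1, n_clip = 2L,
                      n_background = 2L, read_length = 36L,
                      n_reads = 2e5, pwm = defaultPwm(),
                      pwm_threshold = 3.0, pwm_pseudocount = 5e-5,
                      sites_per_gene_mean = 2,
                      conversion_rate = 0.5, background_mix = 0.1,
                      retention = c("score-proportional", "literal"),
                      seed = 1L) {
    retention <- match.arg(retention)
    stopifnot(conversion_rate >= 0, conversion_rate <= 1,
        background_mix >= 0, background_mix <= 1,
        n_genes > 0, n_reads > 0, read_length > 0)
    as.list(environment())
}

#' Default PUM2-like position weight matrix
#'
#' An 8-column probability matrix for the consensus TGTANATA (the DNA
#' rendering of the UGUANAUA recognition element), with the fourth
#' position fixed to A - the crosslink position at which the simulator
#' introduces A-to-T conversions - and a fully degenerate fifth
#' position.
#'
#' @return 4 x 8 numeric matrix with rows A, C, G, T.
#' @export
defaultPwm <- function() {
    cons <- c("T", "G", "T", "A", "N", "A", "T", "A")
    pwm <- matrix(0.01, 4L, length(cons),
        dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(cons)) {
        if (cons[j] == "N") pwm[, j] <- 0.25
        else pwm[cons[j], j] <- 0.97
    }
    pwm
}

#' Read a PWM from a tab-separated text file
#'
#' Expects four rows labelled A, C, G, T with one probability column
#' per motif position.
#'
#' @param path File path.
#' @return 4 x width numeric matrix.
#' @export
readPwm <- function(path) {
    m <- as.matrix(utils::read.table(path, row.names = 1L))
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    colnames(m) <- NULL
    m
}

#' Draw log-normal base gene expressions
#'
#' @param n_genes Number of genes.
#' @param log_mean,log_var Mean and variance of the log expression.
#' @return Numeric vector of abundances exp(N(log_mean, log_var)).
#' @export
drawGeneExpressions <- function(n_genes, log_mean = 10, log_var = 4) {
    exp(rnorm(n_genes, mean = log_mean, sd = sqrt(log_var)))
}

#' Draw negative-binomial replicate counts
#'
#' Counts for each gene and replicate from a negative binomial with
#' mean equal to the base abundance and variance
#' \eqn{\mu + c\mu^2}.
#'
#' @param abundance Per-gene base abundances.
#' @param n_replicates Number of replicates (default 6).
#' @param dispersion Overdispersion c (default 0.1).
#' @return Genes x replicates integer matrix.
#' @export
drawReplicateCounts <- function(abundance, n_replicates = 6L,
                                dispersion = 0.1) {
    n <- length(abundance)
    matrix(rnbinom(n * n_replicates, mu = abundance,
        size = 1 / dispersion), n, n_replicates)
}

# ---- PWM scoring ----------------------------------------------------

.BASES <- c("A", "C", "G", "T")

.seqToInt <- function(sequence) {
    if (is(sequence, "DNAString") || is(sequence, "DNAStringSet"))
        sequence <- as.character(sequence)[1]
    match(strsplit(toupper(sequence), "")[[1]], .BASES)
}

# log2-odds column matrix with pseudocount, uniform background
.pwmLogOdds <- function(pwm, pseudocount = 5e-5) {
    p <- pwm + pseudocount
    p <- sweep(p, 2L, colSums(p), "/")
    log2(p / 0.25)
}

.pwmScoresInt <- function(seq_int, lom) {
    L <- ncol(lom)
    n <- length(seq_int) - L + 1L
    if (n < 1L) return(numeric())
    sc <- numeric(n)
    for (j in seq_len(L))
        sc <- sc + lom[cbind(seq_int[seq_len(n) + j - 1L], j)]
    sc
}

#' Score a sequence with a PWM
#'
#' Log2-odds scoring against a uniform background, with a pseudocount
#' added to the PWM probabilities; forward strand only.
#'
#' @param sequence Character string or Biostrings DNAString.
#' @param pwm 4 x width probability matrix (rows A, C, G, T).
#' @param pseudocount Added to probabilities before normalization
#'   (default 5e-5).
#' @param threshold Match threshold on the log2-odds score
#'   (default 3.0).
#' @return List with \code{scores} (per start position) and
#'   \code{matches} (start positions scoring at least the threshold).
#' @export
scorePwm <- function(sequence, pwm, pseudocount = 5e-5,
                     threshold = 3.0) {
    seq_int <- .seqToInt(sequence)
    sc <- .pwmScoresInt(seq_int, .pwmLogOdds(pwm, pseudocount))
    list(scores = sc, matches = which(sc >= threshold))
}

# ---- library simulation --------------------------------------------

#' Simulate CLIP and background libraries with known crosslink sites
#'
#' Generates a random genome with planted motif instances, draws base
#' gene expressions and per-replicate transcript counts, samples
#' uniform read fragments for six replicate libraries, turns two of
#' them into CLIP libraries by retaining only motif-overlapping reads
#' (with score-dependent retention) and introducing A-to-T conversions
#' at the fourth motif base in a configurable fraction of
#' crosslink-covering reads, and admixes reads from the two held-out
#' libraries into the CLIP libraries as non-specific background.
#'
#' @param config A list from [simConfig()].
#' @return List with elements \code{genome} (DNAStringSet),
#'   \code{genes} (GRanges with \code{gene_id}), \code{readsets}
#'   (named list of [ReadSet-class]), \code{roles},
#'   \code{truth} (abundances, crosslink sites, per-library conversion
#'   tallies) and \code{config}.
#' @export
simulateClipData <- function(config = simConfig()) {
    set.seed(config$seed)
    gap <- 200L
    lens <- sample(seq(config$gene_length_range[1],
        config$gene_length_range[2]), config$n_genes, replace = TRUE)
    starts <- gap + cumsum(c(0L, head(lens + gap, -1L)))
    genome_len <- starts[config$n_genes] + lens[config$n_genes] + gap
    seq_int <- sample.int(4L, genome_len, replace = TRUE)

    # plant motif instances sampled from the PWM columns
    L <- ncol(config$pwm)
    site_list <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
        n_sites <- 1L + rpois(1L, max(config$sites_per_gene_mean - 1, 0))
        margin <- config$read_length + 5L
        lo <- starts[g] + margin
        hi <- starts[g] + lens[g] - 1L - margin - L
        if (hi <= lo) next
        pos <- sort(sample(lo:hi, n_sites, replace = TRUE))
        pos <- pos[c(TRUE, diff(pos) >= 4L * L)]
        for (p in pos)
            seq_int[p + seq_len(L) - 1L] <- apply(config$pwm, 2L,
                function(col) sample.int(4L, 1L, prob = col))
        site_list[[g]] <- pos
    }

    lom <- .pwmLogOdds(config$pwm, config$pwm_pseudocount)
    scores <- .pwmScoresInt(seq_int, lom)
    match_pos <- which(scores >= config$pwm_threshold)
    if (!length(match_pos))
        stop("PWM produced no matches in the simulated genome; ",
             "plant more or stronger motif instances")
    match_score <- scores[match_pos]
    smin <- min(match_score); smax <- max(match_score)
    crosslink <- match_pos + 3L  # 4th base of each motif match

    gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
    genes <- GenomicRanges::GRanges("simchr",
        IRanges::IRanges(start = starts, width = lens), strand = "+",
        gene_id = gene_ids)

    abundance <- drawGeneExpressions(config$n_genes,
        config$expression_log_mean, config$expression_log_var)
    n_rep <- config$n_clip + config$n_background + 2L
    counts <- drawReplicateCounts(abundance, n_rep,
        config$replicate_dispersion)

    draw_fragments <- function(rep_idx) {
        wgt <- counts[, rep_idx] * as.numeric(lens)
        if (sum(wgt) == 0) wgt <- rep(1, config$n_genes)
        gene_of <- sample.int(config$n_genes, config$n_reads,
            replace = TRUE, prob = wgt)
        span <- lens[gene_of] - config$read_length
        off <- floor(runif(config$n_reads) * (span + 1L))
        s <- starts[gene_of] + as.integer(off)
        data.frame(gene = gene_of, start = s,
            end = s + config$read_length - 1L)
    }

    # which motif match (if any) does each read overlap; returns the
    # best-scoring overlapped match index per read, NA when none
    best_match <- function(fr) {
        ov <- IRanges::findOverlaps(
            IRanges::IRanges(fr$start, fr$end),
            IRanges::IRanges(match_pos, match_pos + L - 1L))
        if (!length(ov))
            return(rep(NA_integer_, nrow(fr)))
        qh <- S4Vectors::queryHits(ov)
        sh <- S4Vectors::subjectHits(ov)
        ord <- order(qh, -match_score[sh])
        first <- !duplicated(qh[ord])
        out <- rep(NA_integer_, nrow(fr))
        out[qh[ord][first]] <- sh[ord][first]
        out
    }

    roles <- c(rep("background", config$n_background),
        rep("CLIP", config$n_clip))
    lib_names <- c(sprintf("bg%d", seq_len(config$n_background)),
        sprintf("clip%d", seq_len(config$n_clip)))
    readsets <- vector("list", length(roles))
    names(readsets) <- lib_names
    conv_tally <- data.frame(lib = character(), covering = integer(),
        converted = integer())

    mk_readset <- function(fr, mm = NULL) {
        ReadSet(chrom = rep("simchr", nrow(fr)), start = fr$start,
            end = fr$end, strand = rep("+", nrow(fr)),
            read_length = rep(config$read_length, nrow(fr)),
            mismatches = mm)
    }

    for (b in seq_len(config$n_background))
        readsets[[b]] <- mk_readset(draw_fragments(b))

    heldout <- lapply(seq_len(2L), function(k)
        draw_fragments(config$n_background + config$n_clip + k))

    for (u in seq_len(config$n_clip)) {
        fr <- draw_fragments(config$n_background + u)
        bm <- best_match(fr)
        fr <- fr[!is.na(bm), , drop = FALSE]
        bm <- bm[!is.na(bm)]
        s <- match_score[bm]
        p <- runif(nrow(fr), smin, smax)
        keep <- if (smax > smin) {
            if (config$retention == "score-proportional") p <= s
            else p >= s
        } else rep(TRUE, nrow(fr))
        fr <- fr[keep, , drop = FALSE]
        bm <- bm[keep]
        # A-to-T conversion at the crosslink (4th motif base) in a
        # Bernoulli(conversion_rate) fraction of covering reads
        xl <- crosslink[bm]
        covers <- fr$start <= xl & fr$end >= xl
        do_conv <- covers & (runif(nrow(fr)) < config$conversion_rate)
        ref <- .BASES[seq_int[xl]]
        convertible <- do_conv & ref != "T"
        mm <- data.frame(
            read = which(convertible),
            gpos = xl[convertible],
            ref = ref[convertible],
            alt = "T",
            offset = xl[convertible] - fr$start[convertible])
        conv_tally <- rbind(conv_tally, data.frame(
            lib = lib_names[config$n_background + u],
            covering = sum(covers), converted = sum(do_conv)))
        # admix non-specific reads from the held-out library so that
        # they make up background_mix of the final CLIP library
        ho <- heldout[[u]]
        n_mix <- min(nrow(ho), round(config$background_mix /
            (1 - config$background_mix) * nrow(fr)))
        if (n_mix > 0) {
            mix <- ho[sample.int(nrow(ho), n_mix), , drop = FALSE]
            fr <- rbind(fr, mix)
        }
        readsets[[config$n_background + u]] <- mk_readset(fr, mm)
    }

    genome <- Biostrings::DNAStringSet(paste(.BASES[seq_int],
        collapse = ""))
    names(genome) <- "simchr"
    truth <- list(
        abundance = setNames(abundance, gene_ids),
        sites = GenomicRanges::GRanges("simchr",
            IRanges::IRanges(crosslink, width = 1L), strand = "+",
            motif_start = match_pos, motif_score = match_score),
        planted = site_list,
        conversions = conv_tally)
    list(genome = genome, genes = genes, readsets = readsets,
        roles = roles, truth = truth, config = config)
}

# ---- writers --------------------------------------------------------

#' Write a simulated dataset to disk
#'
#' Emits the genome FASTA, gene GTF, one SAM file per library (with MD
#' and NM tags so the import path reconstructs mismatches), a BED of
#' true crosslink sites and a JSON of true abundances.
#'
#' @param sim Result of [simulateClipData()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of file paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    paths$genome <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim$genome, paths$genome)
    paths$genes <- file.path(dir, "genes.gtf")
    .writeGtf(sim$genes, paths$genes)
    genome_chr <- as.character(sim$genome[[1]])
    for (w in seq_along(sim$readsets)) {
        nm <- names(sim$readsets)[w]
        paths[[nm]] <- file.path(dir, paste0(nm, ".sam"))
        .writeSam(sim$readsets[[w]], genome_chr,
            width(sim$genome)[1], paths[[nm]])
    }
    paths$sites <- file.path(dir, "truth_sites.bed")
    sites <- sim$truth$sites
    utils::write.table(data.frame(
        chrom = as.character(GenomicRanges::seqnames(sites)),
        start = GenomicRanges::start(sites) - 1L,
        end = GenomicRanges::end(sites),
        name = sprintf("site%d", seq_along(sites)),
        score = round(sites$motif_score, 3),
        strand = as.character(GenomicRanges::strand(sites))),
        paths$sites, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    paths$abundance <- file.path(dir, "truth_abundance.json")
    jsonlite::write_json(as.list(sim$truth$abundance),
        paths$abundance, auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

.writeGtf <- function(genes, path) {
    lines <- character()
    for (type in c("gene", "exon")) {
        lines <- c(lines, sprintf(
            "%s\tclipHMM_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            as.character(GenomicRanges::seqnames(genes)), type,
            GenomicRanges::start(genes), GenomicRanges::end(genes),
            as.character(GenomicRanges::strand(genes)),
            sprintf("gene_id \"%s\"; transcript_id \"%s.t1\";",
                genes$gene_id, genes$gene_id)))
    }
    writeLines(lines, path)
}

.writeSam <- function(readset, genome_chr, chrom_len, path) {
    gr <- readset@reads
    n <- length(gr)
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
        sprintf("@SQ\tSN:simchr\tLN:%d", chrom_len))
    if (n == 0L) { writeLines(hdr, path); return(invisible(path)) }
    ord <- order(GenomicRanges::start(gr))
    s <- GenomicRanges::start(gr)[ord]
    e <- GenomicRanges::end(gr)[ord]
    rl <- S4Vectors::mcols(gr)$read_length[ord]
    seqs <- substring(genome_chr, s, e)
    mm <- readset@mismatches
    md <- sprintf("%d", rl)
    nm <- integer(n)
    if (nrow(mm)) {
        ridx <- match(mm$read, ord)
        # apply the alternative base into the read sequence
        for (k in seq_len(nrow(mm))) {
            i <- ridx[k]
            off <- mm$gpos[k] - s[i]
            substr(seqs[i], off + 1L, off + 1L) <- mm$alt[k]
        }
        agg <- split(seq_len(nrow(mm)), ridx)
        for (i_chr in names(agg)) {
            i <- as.integer(i_chr)
            rows <- agg[[i_chr]]
            offs <- sort(mm$gpos[rows] - s[i])
            refs <- mm$ref[rows][order(mm$gpos[rows] - s[i])]
            parts <- character()
            prev <- 0L
            for (k in seq_along(offs)) {
                parts <- c(parts, sprintf("%d%s", offs[k] - prev,
                    refs[k]))
                prev <- offs[k] + 1L
            }
            md[i] <- paste0(paste(parts, collapse = ""), rl[i] - prev)
            nm[i] <- length(rows)
        }
    }
    recs <- sprintf(
        "r%06d\t0\tsimchr\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tMD:Z:%s\tNM:i:%d",
        seq_len(n), s, rl, seqs, md, nm)
    writeLines(c(hdr, recs), path)
    invisible(path)
}
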