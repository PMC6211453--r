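test_that("read filter drops high-mismatch and wrong-strand reads", {
    # panel: mismatch counts 0, 1, 2, 3 on the gene strand plus two
    # wrong-strand reads
    mm <- do.call(rbind, lapply(seq_len(6L), function(r) {
        k <- c(0L, 1L, 2L, 3L, 0L, 1L)[r]
        if (k == 0L) return(NULL)
        data.frame(read = r, gpos = 100L + seq_len(k),
            ref = "T", alt = "C", offset = 10L + seq_len(k))
    }))
    rs <- make_reads(data.frame(
        chrom = "chr1", start = rep(95L, 6L), end = rep(124L, 6L),
        strand = c("+", "+", "+", "+", "-", "-"),
        read_length = 30L), mismatches = mm)
    keep <- filterReads(rs, gene_strand = "+")
    expect_identical(keep, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_identical(sum(keep), 3L)
    # reads without strand information pass regardless of gene strand
    rs2 <- make_reads(data.frame(chrom = "chr1", start = 1L,
        end = 30L, strand = "*", read_length = 30L))
    expect_true(filterReads(rs2, "+"))
    expect_true(filterReads(rs2, "-"))
})

test_that("diagnostic events cover conversions, deletions and ends", {
    cats <- eventCategories()
    rs <- make_reads(
        data.frame(chrom = "chr1", start = 101L, end = 130L,
            strand = "+", read_length = 30L),
        mismatches = data.frame(read = 1L, gpos = 116L, ref = "T",
            alt = "C", offset = 15L))
    ev <- extractDiagnosticEvents(rs)
    expect_identical(nrow(ev), 3L)
    expect_setequal(cats[ev$cat], c("T>C", "5p_end", "3p_end"))
    expect_identical(ev$gpos[ev$cat == match("T>C", cats)], 116L)
    expect_identical(ev$gpos[ev$cat == match("5p_end", cats)], 101L)
    expect_identical(ev$gpos[ev$cat == match("3p_end", cats)], 130L)
})

test_that("conversions in the first or last two read bases are dropped", {
    # single mismatch at offset 0: only the end events remain
    rs <- make_reads(
        data.frame(chrom = "chr1", start = 101L, end = 130L,
            strand = "+", read_length = 30L),
        mismatches = data.frame(read = 1L, gpos = 101L, ref = "A",
            alt = "G", offset = 0L))
    ev <- extractDiagnosticEvents(rs)
    expect_identical(sort(eventCategories()[ev$cat]),
        sort(c("5p_end", "3p_end")))
    # offsets {1, 2, 28, 29} of a 30-mer: the first/last-two rule
    # drops 1, 28 and 29, so exactly the offset-2 conversion survives
    offs <- c(1L, 2L, 28L, 29L)
    rs2 <- make_reads(
        data.frame(chrom = "chr1", start = 101L, end = 130L,
            strand = "+", read_length = 30L),
        mismatches = data.frame(read = 1L, gpos = 101L + offs,
            ref = "T", alt = "C", offset = offs))
    ev2 <- extractDiagnosticEvents(rs2)
    conv <- ev2[ev2$cat <= 12L, ]
    expect_identical(nrow(conv), 1L)
    expect_identical(conv$gpos, 103L)
    # offsets {2, 27} both survive
    rs3 <- make_reads(
        data.frame(chrom = "chr1", start = 101L, end = 130L,
            strand = "+", read_length = 30L),
        mismatches = data.frame(read = 1L, gpos = c(103L, 128L),
            ref = "T", alt = "C", offset = c(2L, 27L)))
    expect_identical(nrow(extractDiagnosticEvents(rs3)) - 2L, 2L)
})

test_that("deletions and read ends are never offset-dropped", {
    rs <- make_reads(
        data.frame(chrom = "chr1", start = 101L, end = 131L,
            strand = "+", read_length = 30L),
        deletions = data.frame(read = 1L, gpos = 101L, ref = "G"))
    ev <- extractDiagnosticEvents(rs)
    expect_true(match("del:G", eventCategories()) %in% ev$cat)
})

test_that("5' end of a minus-strand read is its rightmost position", {
    rs <- make_reads(data.frame(chrom = "chr1", start = 101L,
        end = 130L, strand = "-", read_length = 30L))
    ev <- extractDiagnosticEvents(rs)
    cats <- eventCategories()
    expect_identical(ev$gpos[ev$cat == match("5p_end", cats)], 130L)
    expect_identical(ev$gpos[ev$cat == match("3p_end", cats)], 101L)
})

test_that("SNP detection pools background coverage and conversions", {
    cats <- eventCategories()
    tc <- match("T>C", cats)
    cov <- matrix(0L, 3L, 2L,
        dimnames = list(NULL, c("bg1", "clip1")))
    cov[1L, 1L] <- 25L   # 25 background reads, 6 conversions (24%)
    cov[2L, 1L] <- 19L   # below the 20-read floor despite 100% conv
    ev <- data.frame(pos = c(1L, 2L), lib = 1L, cat = tc,
        count = c(6L, 19L))
    t <- make_tensor(cov, ev, roles = c("background", "CLIP"))
    mask <- detectSnpPositions(t)
    expect_identical(mask, c(TRUE, FALSE, FALSE))
    # masking keeps coverage and removes events at masked positions
    t2 <- maskSnps(t, mask)
    expect_identical(t2@coverage, cov)
    expect_false(any(t2@events$pos == 1L))
    # no background libraries: masking must fail loudly
    t3 <- make_tensor(cov, ev, roles = c("CLIP", "CLIP"))
    expect_error(detectSnpPositions(t3), "background")
})

test_that("tensor pileup matches a hand tally and is order-invariant", {
    gene <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(1L, 60L), strand = "+", gene_id = "g1")
    # library 1: two identical reads at 10-39; library 2: one read at
    # 20-49 with a T>C at 25 and one at 40-59
    lib1 <- make_reads(data.frame(chrom = "chr1",
        start = c(10L, 10L), end = c(39L, 39L), strand = "+",
        read_length = 30L))
    lib2 <- make_reads(data.frame(chrom = "chr1",
        start = c(20L, 40L), end = c(49L, 59L), strand = "+",
        read_length = c(30L, 20L)),
        mismatches = data.frame(read = 1L, gpos = 25L, ref = "T",
            alt = "C", offset = 5L))
    t <- buildSiteTensor(list(a = lib1, b = lib2), gene,
        lib_roles = c("CLIP", "background"))
    expect_identical(unname(t@coverage[10:39, 1L]), rep(2L, 30L))
    expect_identical(sum(t@coverage[, 1L]), 60L)
    expect_identical(unname(t@coverage[25L, 2L]), 1L)
    expect_identical(unname(t@coverage[45L, 2L]), 2L)
    tc <- match("T>C", eventCategories())
    expect_identical(
        t@events$count[t@events$pos == 25L & t@events$cat == tc], 1L)
    # permutation of read order changes nothing
    lib2r <- make_reads(data.frame(chrom = "chr1",
        start = c(40L, 20L), end = c(59L, 49L), strand = "+",
        read_length = c(20L, 30L)),
        mismatches = data.frame(read = 2L, gpos = 25L, ref = "T",
            alt = "C", offset = 5L))
    t2 <- buildSiteTensor(list(a = lib1, b = lib2r), gene,
        lib_roles = c("CLIP", "background"))
    expect_identical(t@coverage, t2@coverage)
    expect_identical(
        t@events[order(t@events$pos, t@events$cat), ],
        t2@events[order(t2@events$pos, t2@events$cat), ],
        ignore_attr = TRUE)
})

test_that("coverage sums equal clipped read footprints per library", {
    gene <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(20L, 49L), strand = "+", gene_id = "g1")
    # one read fully inside, one hanging off each end
    lib <- make_reads(data.frame(chrom = "chr1",
        start = c(25L, 10L, 45L), end = c(34L, 24L, 59L),
        strand = "+", read_length = c(10L, 15L, 15L)))
    t <- buildSiteTensor(list(a = lib), gene, lib_roles = "CLIP")
    expect_identical(sum(t@coverage), 10L + 5L + 5L)
})

test_that("SNP-masked positions keep coverage but no events", {
    gene <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(1L, 40L), strand = "+", gene_id = "g1")
    lib <- make_reads(data.frame(chrom = "chr1", start = 11L,
        end = 40L, strand = "+", read_length = 30L),
        mismatches = data.frame(read = 1L, gpos = 20L, ref = "T",
            alt = "C", offset = 9L))
    mask <- rep(FALSE, 40L); mask[20L] <- TRUE
    t <- buildSiteTensor(list(a = lib), gene, lib_roles = "CLIP",
        snp_mask = mask)
    expect_identical(unname(t@coverage[20L, 1L]), 1L)
    expect_false(any(t@events$pos == 20L & t@events$cat <= 12L))
})

test_that("miRNA-masked positions are zeroed entirely", {
    gene <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(1L, 40L), strand = "+", gene_id = "g1")
    lib <- make_reads(data.frame(chrom = "chr1", start = 11L,
        end = 40L, strand = "+", read_length = 30L))
    mask <- rep(FALSE, 40L); mask[15:25] <- TRUE
    t <- buildSiteTensor(list(a = lib), gene, lib_roles = "CLIP",
        mirna_mask = mask)
    expect_true(all(t@coverage[15:25, ] == 0L))
    expect_identical(unname(t@coverage[14L, 1L]), 1L)
})

test_that("reads outside the gene span are skipped with a warning", {
    gene <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(100L, 140L), strand = "+", gene_id = "g1")
    lib <- make_reads(data.frame(chrom = "chr1",
        start = c(110L, 500L), end = c(139L, 529L), strand = "+",
        read_length = 30L))
    expect_warning(
        t <- buildSiteTensor(list(a = lib), gene, lib_roles = "CLIP"),
        "outside gene span")
    expect_identical(sum(t@coverage), 30L)
})

test_that("SAM round trip preserves reads, mismatches and pileups", {
    cfg <- simConfig(n_genes = 4L, n_reads = 1500L, seed = 3L)
    sim <- simulateClipData(cfg)
    dir <- withr::local_tempdir()
    paths <- writeSimulation(sim, dir)
    rs_mem <- sim$readsets$clip1
    rs_sam <- importReads(paths$clip1)
    expect_identical(length(rs_sam), length(rs_mem))
    ord_mem <- order(GenomicRanges::start(rs_mem@reads))
    expect_identical(
        GenomicRanges::start(rs_sam@reads),
        GenomicRanges::start(rs_mem@reads)[ord_mem])
    mm_mem <- rs_mem@mismatches
    mm_sam <- rs_sam@mismatches
    expect_identical(nrow(mm_sam), nrow(mm_mem))
    expect_identical(sort(mm_sam$gpos), sort(mm_mem$gpos))
    expect_identical(sort(mm_sam$offset), sort(mm_mem$offset))
    expect_true(all(mm_sam$alt == "T"))
    # tensors built from SAM match tensors built in memory
    t_sam <- readClipData(
        list(clip1 = paths$clip1, bg1 = paths$bg1),
        roles = c("CLIP", "background"), annotation = paths$genes)
    t_mem <- readClipData(
        list(clip1 = sim$readsets$clip1, bg1 = sim$readsets$bg1),
        roles = c("CLIP", "background"), annotation = sim$genes)
    for (g in names(t_mem)) {
        expect_identical(unname(t_sam[[g]]@coverage),
            unname(t_mem[[g]]@coverage))
        expect_identical(t_sam[[g]]@events$count,
            t_mem[[g]]@events$count)
    }
})

test_that("MD/CIGAR parsing handles deletions and soft clips", {
    sam <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
        # 10M2D10M with a mismatch in the second block
        paste("d1", "0", "chr1", "101", "255", "10M2D10M", "*", "0",
            "0", paste(rep("A", 20L), collapse = ""), "*",
            "MD:Z:10^CT4G5", "NM:i:3", sep = "\t"),
        # 3S17M soft-clipped read, mismatch at aligned base 5
        paste("s1", "0", "chr1", "201", "255", "3S17M", "*", "0",
            "0", paste(rep("A", 20L), collapse = ""), "*",
            "MD:Z:4T12", "NM:i:1", sep = "\t"))
    path <- withr::local_tempfile(fileext = ".sam")
    writeLines(sam, path)
    rs <- importReads(path)
    expect_identical(length(rs), 2L)
    dl <- rs@deletions
    expect_identical(dl$gpos, c(111L, 112L))
    expect_identical(dl$ref, c("C", "T"))
    mm <- rs@mismatches
    expect_identical(mm$gpos[mm$read == 1L], 117L)
    expect_identical(mm$ref[mm$read == 1L], "G")
    # soft clip: aligned base 5 is query offset 3 + 4 (0-based 7)
    expect_identical(mm$gpos[mm$read == 2L], 205L)
    expect_identical(mm$offset[mm$read == 2L], 7L)
})

test_that("overlap masks mark regions shared by two genes", {
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1L, 41L), c(60L, 100L)),
        strand = c("+", "-"), gene_id = c("gA", "gB"))
    lib <- make_reads(data.frame(chrom = "chr1", start = 45L,
        end = 54L, strand = "+", read_length = 10L))
    tns <- readClipData(list(clip1 = lib), roles = "CLIP",
        annotation = genes)
    expect_identical(which(tns$gA@overlap_mask), 41:60)
    expect_identical(which(tns$gB@overlap_mask), 1:20)
})
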