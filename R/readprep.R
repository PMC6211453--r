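#' Read filter for diagnostic-event robustness
#'
#' A read is kept when it has at most \code{max_mismatches} mismatches
#' and, when strand information is available, maps to the same strand
#' as the gene under consideration.
#'
#' @param readset A [ReadSet-class].
#' @param gene_strand \code{"+"} or \code{"-"}; the gene's strand.
#' @param max_mismatches Maximum mismatch count (default 2).
#' @return Logical vector, one entry per read.
#' @export
filterReads <- function(readset, gene_strand, max_mismatches = 2L) {
    st <- as.character(GenomicRanges::strand(readset@reads))
    nmm <- S4Vectors::mcols(readset@reads)$n_mismatch
    nmm <= max_mismatches & (st == "*" | st == gene_strand)
}

#' Extract diagnostic events from aligned reads
#'
#' Produces one event per qualifying mismatch (12 substitution
#' categories), one per deleted reference base (4 categories), plus a
#' 5'-end and a 3'-end event at each read's terminal genomic positions
#' (2 truncation categories).  Conversions falling in the first or last
#' two bases of a read are dropped as likely mis-mapped read ends;
#' deletions and end events are never offset-dropped.
#'
#' @param readset A [ReadSet-class] of reads that passed
#'   [filterReads()].
#' @return data.frame with columns \code{read}, \code{gpos},
#'   \code{cat} (index into [eventCategories()]).
#' @export
extractDiagnosticEvents <- function(readset) {
    cats <- eventCategories()
    gr <- readset@reads
    rl <- S4Vectors::mcols(gr)$read_length
    out <- list()

    mm <- readset@mismatches
    if (nrow(mm)) {
        lens <- rl[mm$read]
        keep <- mm$offset >= 2L & mm$offset <= lens - 3L
        mm <- mm[keep, , drop = FALSE]
        if (nrow(mm)) {
            cat_idx <- match(paste0(mm$ref, ">", mm$alt), cats)
            ok <- !is.na(cat_idx)
            out$mm <- data.frame(read = mm$read[ok], gpos = mm$gpos[ok],
                cat = cat_idx[ok])
        }
    }
    dl <- readset@deletions
    if (nrow(dl)) {
        cat_idx <- match(paste0("del:", dl$ref), cats)
        ok <- !is.na(cat_idx)
        out$dl <- data.frame(read = dl$read[ok], gpos = dl$gpos[ok],
            cat = cat_idx[ok])
    }
    if (length(gr)) {
        st <- as.character(GenomicRanges::strand(gr))
        s <- GenomicRanges::start(gr)
        e <- GenomicRanges::end(gr)
        five <- ifelse(st == "-", e, s)
        three <- ifelse(st == "-", s, e)
        out$ends <- data.frame(
            read = rep(seq_along(gr), 2L),
            gpos = c(five, three),
            cat = rep(match(c("5p_end", "3p_end"), cats),
                each = length(gr)))
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(read = integer(), gpos = integer(),
            cat = integer())
    rownames(res) <- NULL
    res[order(res$read, res$gpos, res$cat), , drop = FALSE]
}

#' Detect likely SNP positions from background libraries
#'
#' A position is flagged as a likely SNP when the pooled background
#' coverage is at least \code{min_reads} and at least a fraction
#' \code{min_frac} of those reads carry a conversion (substitution)
#' event there.  Flagged positions are excluded from diagnostic-event
#' modelling but keep their coverage.
#'
#' @param tensor A [SiteTensor-class] containing at least one
#'   background library.
#' @param min_reads Minimum pooled background coverage (default 20).
#' @param min_frac Minimum pooled conversion fraction (default 0.2).
#' @return Logical mask, one entry per position.
#' @export
detectSnpPositions <- function(tensor, min_reads = 20L, min_frac = 0.2) {
    bg <- which(tensor@lib_roles == "background")
    if (!length(bg))
        stop("SNP masking requires at least one background library")
    cov <- rowSums(tensor@coverage[, bg, drop = FALSE])
    conv <- numeric(tensor@n_pos)
    ev <- tensor@events
    if (nrow(ev)) {
        sub_cats <- seq_len(12L)  # the 12 substitution categories
        ev <- ev[ev$lib %in% bg & ev$cat %in% sub_cats, , drop = FALSE]
        if (nrow(ev)) {
            agg <- rowsum(ev$count, group = ev$pos)
            conv[as.integer(rownames(agg))] <- agg[, 1]
        }
    }
    cov >= min_reads & conv >= min_frac * cov
}

#' Apply a SNP mask to a tensor
#'
#' Sets the tensor's SNP mask and removes event records at masked
#' positions; coverage is retained.
#'
#' @param tensor A [SiteTensor-class].
#' @param mask Logical mask per position; default: detect from the
#'   background libraries via [detectSnpPositions()].
#' @param ... Passed to [detectSnpPositions()].
#' @return The updated \code{SiteTensor}.
#' @export
maskSnps <- function(tensor, mask = NULL, ...) {
    if (is.null(mask)) mask <- detectSnpPositions(tensor, ...)
    stopifnot(length(mask) == tensor@n_pos)
    tensor@snp_mask <- mask
    if (nrow(tensor@events))
        tensor@events <- tensor@events[!mask[tensor@events$pos], ,
            drop = FALSE]
    tensor
}

#' Build the per-gene coverage and event tensor
#'
#' Computes, for one gene, the position-by-library coverage matrix
#' (full read footprints, clipped to the gene span) and aggregated
#' diagnostic-event counts.  Positions under the SNP mask contribute no
#' event counts but keep coverage; positions under the miRNA mask are
#' zeroed entirely (treated as having no coverage or events).
#'
#' @param reads_by_lib Named list of [ReadSet-class], one per library,
#'   already passed through [filterReads()] for this gene.
#' @param gene A length-1 [GenomicRanges::GRanges] with metadata column
#'   \code{gene_id} giving the gene span.
#' @param lib_roles Character vector (\code{"CLIP"}/\code{"background"})
#'   parallel to \code{reads_by_lib}.
#' @param snp_mask,mirna_mask,overlap_mask Optional logical masks over
#'   the gene span (default all-FALSE).
#' @return A [SiteTensor-class].
#' @export
buildSiteTensor <- function(reads_by_lib, gene, lib_roles,
                            snp_mask = NULL, mirna_mask = NULL,
                            overlap_mask = NULL) {
    stopifnot(length(gene) == 1L)
    gstart <- GenomicRanges::start(gene)
    gend <- GenomicRanges::end(gene)
    n_pos <- gend - gstart + 1L
    n_lib <- length(reads_by_lib)
    if (is.null(snp_mask)) snp_mask <- rep(FALSE, n_pos)
    if (is.null(mirna_mask)) mirna_mask <- rep(FALSE, n_pos)
    if (is.null(overlap_mask)) overlap_mask <- rep(FALSE, n_pos)
    lib_names <- names(reads_by_lib)
    if (is.null(lib_names)) lib_names <- paste0("lib", seq_len(n_lib))

    cov <- matrix(0L, n_pos, n_lib, dimnames = list(NULL, lib_names))
    ev_list <- list()
    n_skipped <- 0L
    for (w in seq_len(n_lib)) {
        rs <- reads_by_lib[[w]]
        if (!length(rs)) next
        s <- GenomicRanges::start(rs@reads)
        e <- GenomicRanges::end(rs@reads)
        chr_ok <- as.character(GenomicRanges::seqnames(rs@reads)) ==
            as.character(GenomicRanges::seqnames(gene))
        inside <- chr_ok & e >= gstart & s <= gend
        n_skipped <- n_skipped + sum(!inside)
        if (!any(inside)) next
        cs <- pmax(s[inside], gstart) - gstart + 1L
        ce <- pmin(e[inside], gend) - gstart + 1L
        # footprint pileup via difference array
        d <- integer(n_pos + 1L)
        d[seq_len(n_pos)] <- tabulate(cs, nbins = n_pos)
        ends <- tabulate(ce + 1L, nbins = n_pos + 1L)
        cov[, w] <- cumsum(d[seq_len(n_pos)] - ends[seq_len(n_pos)])

        ev <- extractDiagnosticEvents(rs[which(inside)])
        if (nrow(ev)) {
            pos_local <- ev$gpos - gstart + 1L
            keep <- pos_local >= 1L & pos_local <= n_pos &
                !snp_mask[pmax(pmin(pos_local, n_pos), 1L)]
            if (any(keep)) {
                key <- paste(pos_local[keep], ev$cat[keep])
                agg <- rowsum(rep(1L, sum(keep)), group = key)
                parts <- do.call(rbind, strsplit(rownames(agg), " "))
                ev_list[[w]] <- data.frame(
                    pos = as.integer(parts[, 1]),
                    lib = w,
                    cat = as.integer(parts[, 2]),
                    count = as.integer(agg[, 1]))
            }
        }
    }
    if (n_skipped > 0L)
        warning(sprintf("gene %s: %d reads outside gene span skipped",
            gene$gene_id, n_skipped))
    events <- do.call(rbind, ev_list)
    if (is.null(events))
        events <- data.frame(pos = integer(), lib = integer(),
            cat = integer(), count = integer())
    if (any(mirna_mask)) {
        cov[mirna_mask, ] <- 0L
        if (nrow(events))
            events <- events[!mirna_mask[events$pos], , drop = FALSE]
    }
    rownames(events) <- NULL
    methods::new("SiteTensor",
        gene_id = as.character(gene$gene_id),
        chrom = as.character(GenomicRanges::seqnames(gene)),
        strand = as.character(GenomicRanges::strand(gene)),
        start = gstart, n_pos = n_pos,
        coverage = cov, events = events,
        lib_names = lib_names, lib_roles = lib_roles,
        snp_mask = snp_mask, mirna_mask = mirna_mask,
        overlap_mask = overlap_mask)
}

#' Load alignments and annotation into per-gene tensors
#'
#' End-to-end loader: imports gene models from GTF/GFF, reads each
#' alignment file, applies the read filter per gene, builds the
#' per-gene tensors, computes the gene-overlap mask, applies the
#' optional miRNA mask and finally the background-derived SNP mask.
#'
#' @param alignments Named list: either file paths (SAM/BAM) or
#'   [ReadSet-class] objects, one per library.
#' @param roles Character vector of \code{"CLIP"}/\code{"background"}
#'   parallel to \code{alignments}.
#' @param annotation Path to a GTF/GFF file, or a
#'   [GenomicRanges::GRanges] of gene spans with metadata column
#'   \code{gene_id}.
#' @param mirna Optional: path to BED/GTF of miRNA genes, or a GRanges.
#' @param max_mismatches Read filter threshold (default 2).
#' @param snp_min_reads,snp_min_frac SNP masking thresholds
#'   (defaults 20 and 0.2).
#' @return Named list of [SiteTensor-class], one per gene.
#' @export
readClipData <- function(alignments, roles, annotation, mirna = NULL,
                         max_mismatches = 2L, snp_min_reads = 20L,
                         snp_min_frac = 0.2) {
    genes <- .asGeneRanges(annotation)
    readsets <- lapply(alignments, function(a)
        if (is(a, "ReadSet")) a else importReads(a))
    mirna_gr <- if (is.null(mirna)) NULL else .asGeneRanges(mirna,
        require_id = FALSE)
    # regions covered by 2+ genes (either strand)
    self_ol <- GenomicRanges::findOverlaps(genes, genes,
        ignore.strand = TRUE)
    self_ol <- self_ol[S4Vectors::queryHits(self_ol) !=
        S4Vectors::subjectHits(self_ol)]

    has_bg <- any(roles == "background")
    # one overlap pass per library, reads assigned to every gene they
    # touch
    hits_by_gene <- lapply(readsets, function(rs) {
        ov <- GenomicRanges::findOverlaps(rs@reads, genes,
            ignore.strand = TRUE)
        split(S4Vectors::queryHits(ov),
            factor(S4Vectors::subjectHits(ov),
                levels = seq_along(genes)))
    })
    tensors <- vector("list", length(genes))
    names(tensors) <- genes$gene_id
    for (gi in seq_along(genes)) {
        gene <- genes[gi]
        n_pos <- GenomicRanges::width(gene)
        per_lib <- lapply(seq_along(readsets), function(w) {
            sel <- readsets[[w]][hits_by_gene[[w]][[gi]]]
            sel[which(filterReads(sel,
                as.character(GenomicRanges::strand(gene)),
                max_mismatches))]
        })
        names(per_lib) <- names(readsets)
        ol_mask <- rep(FALSE, n_pos)
        others <- S4Vectors::subjectHits(self_ol)[
            S4Vectors::queryHits(self_ol) == gi]
        if (length(others)) {
            ov <- GenomicRanges::pintersect(
                rep(gene, length(others)), genes[others],
                ignore.strand = TRUE)
            for (k in seq_along(ov)) {
                lo <- GenomicRanges::start(ov)[k] -
                    GenomicRanges::start(gene) + 1L
                hi <- GenomicRanges::end(ov)[k] -
                    GenomicRanges::start(gene) + 1L
                ol_mask[lo:hi] <- TRUE
            }
        }
        mi_mask <- rep(FALSE, n_pos)
        if (!is.null(mirna_gr)) {
            ovm <- GenomicRanges::findOverlaps(gene, mirna_gr,
                ignore.strand = TRUE)
            for (k in S4Vectors::subjectHits(ovm)) {
                lo <- max(GenomicRanges::start(mirna_gr)[k],
                    GenomicRanges::start(gene)) -
                    GenomicRanges::start(gene) + 1L
                hi <- min(GenomicRanges::end(mirna_gr)[k],
                    GenomicRanges::end(gene)) -
                    GenomicRanges::start(gene) + 1L
                mi_mask[lo:hi] <- TRUE
            }
        }
        tns <- buildSiteTensor(per_lib, gene, roles,
            mirna_mask = mi_mask, overlap_mask = ol_mask)
        if (has_bg)
            tns <- maskSnps(tns, min_reads = snp_min_reads,
                min_frac = snp_min_frac)
        tensors[[gi]] <- tns
    }
    tensors
}

.asGeneRanges <- function(annotation, require_id = TRUE) {
    if (is(annotation, "GRanges")) {
        gr <- annotation
    } else {
        gr <- rtracklayer::import(annotation)
        if ("type" %in% names(S4Vectors::mcols(gr)) &&
            any(gr$type == "gene"))
            gr <- gr[gr$type == "gene"]
    }
    if (require_id && is.null(gr$gene_id))
        stop("annotation must carry a gene_id metadata column")
    gr
}
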