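#' ReadSet: aligned reads with mismatch and deletion detail
#'
#' A light container for aligned reads carrying the per-read detail the
#' diagnostic-event model needs: mismatches (with read offset, genomic
#' position, reference and alternative base) and deletions.  Reads are
#' stored as a [GenomicRanges::GRanges] with metadata columns
#' \code{read_length} and \code{n_mismatch}; mismatches and deletions
#' are data.frames keyed by read index.
#'
#' @slot reads GRanges, one range per read (aligned reference span).
#' @slot mismatches data.frame with columns \code{read}, \code{gpos},
#'   \code{ref}, \code{alt}, \code{offset} (0-based offset in the read).
#' @slot deletions data.frame with columns \code{read}, \code{gpos},
#'   \code{ref}.
#' @export
setClass("ReadSet",
    representation(
        reads = "GRanges",
        mismatches = "data.frame",
        deletions = "data.frame"
    )
)

setValidity("ReadSet", function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object@reads)
    if (!all(c("read_length", "n_mismatch") %in% names(mc)))
        msg <- c(msg, "reads needs mcols read_length and n_mismatch")
    mm <- object@mismatches
    if (nrow(mm)) {
        if (!all(c("read", "gpos", "ref", "alt", "offset") %in% names(mm)))
            msg <- c(msg, "mismatches needs read, gpos, ref, alt, offset")
        else {
            rl <- mc$read_length[mm$read]
            if (any(mm$offset < 0 | mm$offset >= rl))
                msg <- c(msg, "mismatch offsets must lie within the read")
        }
    }
    dl <- object@deletions
    if (nrow(dl) && !all(c("read", "gpos", "ref") %in% names(dl)))
        msg <- c(msg, "deletions needs read, gpos, ref")
    if (length(msg)) msg else TRUE
})

#' @describeIn ReadSet Show a compact summary.
#' @param object A \code{ReadSet}.
#' @export
setMethod("show", "ReadSet", function(object) {
    cat(sprintf("ReadSet: %d reads, %d mismatches, %d deletions\n",
        length(object@reads), nrow(object@mismatches),
        nrow(object@deletions)))
})

#' @describeIn ReadSet Number of reads.
#' @param x A \code{ReadSet}.
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

#' Construct a ReadSet
#'
#' @param chrom,start,end,strand Per-read alignment span (1-based,
#'   closed interval on the reference).
#' @param read_length Per-read length in bases.
#' @param mismatches data.frame with columns \code{read}, \code{gpos},
#'   \code{ref}, \code{alt}, \code{offset}; may be empty.
#' @param deletions data.frame with columns \code{read}, \code{gpos},
#'   \code{ref}; may be empty.
#' @return A [ReadSet-class].
#' @export
ReadSet <- function(chrom, start, end, strand, read_length,
                    mismatches = NULL, deletions = NULL) {
    n <- length(start)
    if (is.null(mismatches))
        mismatches <- data.frame(read = integer(), gpos = integer(),
            ref = character(), alt = character(), offset = integer())
    if (is.null(deletions))
        deletions <- data.frame(read = integer(), gpos = integer(),
            ref = character())
    nmm <- integer(n)
    if (nrow(mismatches)) {
        tab <- tabulate(mismatches$read, nbins = n)
        nmm <- tab
    }
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = strand,
        read_length = as.integer(read_length),
        n_mismatch = nmm)
    methods::new("ReadSet", reads = gr, mismatches = mismatches,
        deletions = deletions)
}

#' Subset a ReadSet by read index
#'
#' @param x A \code{ReadSet}.
#' @param i Integer or logical index over reads.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = FALSE) {
    idx <- seq_along(x@reads)[i]
    remap <- integer(length(x@reads))
    remap[idx] <- seq_along(idx)
    mm <- x@mismatches[x@mismatches$read %in% idx, , drop = FALSE]
    if (nrow(mm)) mm$read <- remap[mm$read]
    dl <- x@deletions[x@deletions$read %in% idx, , drop = FALSE]
    if (nrow(dl)) dl$read <- remap[dl$read]
    methods::new("ReadSet", reads = x@reads[idx], mismatches = mm,
        deletions = dl)
})

# ---- SAM/BAM import -------------------------------------------------

#' Import aligned reads from SAM or BAM
#'
#' Reads an alignment file and reconstructs per-read mismatch and
#' deletion detail from the CIGAR string and the MD tag.  SAM files are
#' converted to BAM in a temporary directory first.
#'
#' @param path Path to a \code{.sam} or \code{.bam} file.
#' @return A [ReadSet-class].
#' @export
importReads <- function(path) {
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        path <- Rsamtools::asBam(path, destination = dest,
            overwrite = TRUE, indexDestination = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
        what = c("rname", "pos", "strand", "cigar", "seq"),
        tag = "MD",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    n <- length(b$pos)
    if (n == 0L)
        return(ReadSet(character(), integer(), integer(), character(),
            integer()))
    ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
    read_len <- GenomicAlignments::cigarWidthAlongQuerySpace(b$cigar)
    md <- b$tag$MD
    if (is.null(md)) md <- rep(NA_character_, n)
    seqs <- as.character(b$seq)
    detail <- .parseAlignmentDetail(b$cigar, md, seqs, b$pos)
    # mismatch offsets from MD walking are in reference orientation;
    # convert to read orientation for minus-strand alignments so the
    # read-end trimming rule sees true read ends
    mm <- detail$mismatches
    if (nrow(mm)) {
        neg <- as.character(b$strand)[mm$read] == "-"
        if (any(neg)) {
            rl <- read_len[mm$read]
            mm$offset[neg] <- rl[neg] - 1L - mm$offset[neg]
        }
        detail$mismatches <- mm
    }
    ReadSet(
        chrom = as.character(b$rname),
        start = b$pos,
        end = b$pos + ref_width - 1L,
        strand = as.character(b$strand),
        read_length = read_len,
        mismatches = detail$mismatches,
        deletions = detail$deletions)
}

# Reconstruct mismatches/deletions from CIGAR + MD + SEQ for a vector
# of reads.  Returns data.frames keyed by read index.
.parseAlignmentDetail <- function(cigar, md, seq, pos) {
    mm_l <- vector("list", length(cigar))
    dl_l <- vector("list", length(cigar))
    for (r in seq_along(cigar)) {
        if (is.na(md[r])) next
        det <- .parseOneAlignment(cigar[r], md[r], seq[r], pos[r])
        if (nrow(det$mm)) { det$mm$read <- r; mm_l[[r]] <- det$mm }
        if (nrow(det$dl)) { det$dl$read <- r; dl_l[[r]] <- det$dl }
    }
    empty_mm <- data.frame(gpos = integer(), alt = character(),
        offset = integer(), ref = character(), read = integer())
    empty_dl <- data.frame(gpos = integer(), ref = character(),
        read = integer())
    mm <- do.call(rbind, c(list(empty_mm), mm_l[!vapply(mm_l, is.null,
        TRUE)]))
    dl <- do.call(rbind, c(list(empty_dl), dl_l[!vapply(dl_l, is.null,
        TRUE)]))
    list(
        mismatches = mm[, c("read", "gpos", "ref", "alt", "offset")],
        deletions = dl[, c("read", "gpos", "ref")])
}

.parseOneAlignment <- function(cigar, md, seq, pos) {
    ops <- .cigarOps(cigar)
    # walk CIGAR: collect, in order, reference positions of M-aligned
    # bases with their query offsets, and reference positions of D bases
    qpos <- 0L   # 0-based offset in query (including soft clips)
    rpos <- pos  # next reference position
    m_gpos <- integer(); m_qoff <- integer()
    d_gpos <- integer(); d_ord <- integer()
    for (k in seq_len(nrow(ops))) {
        op <- ops$op[k]; len <- ops$len[k]
        if (op %in% c("M", "=", "X")) {
            m_gpos <- c(m_gpos, rpos + seq_len(len) - 1L)
            m_qoff <- c(m_qoff, qpos + seq_len(len) - 1L)
            rpos <- rpos + len; qpos <- qpos + len
        } else if (op %in% c("I", "S")) {
            qpos <- qpos + len
        } else if (op %in% c("D", "N")) {
            if (op == "D") d_gpos <- c(d_gpos, rpos + seq_len(len) - 1L)
            rpos <- rpos + len
        } else if (op %in% c("H", "P")) {
            # consumes neither
        } else stop("unsupported CIGAR op: ", op)
    }
    # walk MD in parallel
    toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
    mi <- 0L  # matched/mismatched M-bases consumed
    di <- 0L  # deletion bases consumed
    bases <- strsplit(seq, "")[[1]]
    mm <- data.frame(gpos = integer(), ref = character(),
        alt = character(), offset = integer())
    dl <- data.frame(gpos = integer(), ref = character())
    for (t in toks) {
        if (grepl("^\\d+$", t)) {
            mi <- mi + as.integer(t)
        } else if (startsWith(t, "^")) {
            refs <- strsplit(substring(t, 2), "")[[1]]
            idx <- di + seq_along(refs)
            dl <- rbind(dl, data.frame(gpos = d_gpos[idx], ref = refs))
            di <- di + length(refs)
        } else {
            mi <- mi + 1L
            off <- m_qoff[mi]
            mm <- rbind(mm, data.frame(gpos = m_gpos[mi], ref = t,
                alt = bases[off + 1L], offset = off))
        }
    }
    list(mm = mm, dl = dl)
}

.cigarOps <- function(cigar) {
    lens <- as.integer(regmatches(cigar,
        gregexpr("\\d+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
    data.frame(op = ops, len = lens)
}
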