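#' Diagnostic-event categories
#'
#' The fixed alphabet of read-level diagnostic events tracked by the
#' package: the 12 nucleotide substitutions, deletion of each reference
#' base, and the 5'/3' read-end (truncation) events.  Count vectors
#' carry one extra trailing slot ("none") holding reads that cover a
#' position without producing any event there, so each per-position
#' vector sums to the read coverage.
#'
#' @return Character vector of the 18 event category names.
#' @export
#' @examples
#' eventCategories()
eventCategories <- function() {
    bases <- c("A", "C", "G", "T")
    subs <- unlist(lapply(bases, function(r)
        paste0(r, ">", setdiff(bases, r))))
    c(subs, paste0("del:", bases), "5p_end", "3p_end")
}

# number of true event categories (M); vectors have M + 1 slots
.N_EVENT_CATEGORIES <- 18L
.STATE_NAMES <- c("P", "B1", "B2", "N")

#' SiteTensor: per-gene coverage and diagnostic-event counts
#'
#' Holds, for one gene, the position-by-library read coverage matrix
#' together with sparse diagnostic-event counts and the position masks
#' used during model fitting (likely SNPs, miRNA overlap, overlap with
#' other genes).  Coordinates are 1-based; local position \code{i}
#' corresponds to genomic position \code{start + i - 1}.
#'
#' @slot gene_id Gene identifier.
#' @slot chrom,strand,start Genomic location of the gene span.
#' @slot n_pos Number of positions in the span.
#' @slot coverage Integer matrix, positions x libraries.
#' @slot events data.frame with columns \code{pos}, \code{lib},
#'   \code{cat}, \code{count}: sparse counts for the 18 true event
#'   categories (indices into [eventCategories()]).  The implicit
#'   "none" slot is coverage minus the per-position event total.
#' @slot lib_names,lib_roles Library names and roles
#'   (\code{"CLIP"} or \code{"background"}).
#' @slot snp_mask,mirna_mask,overlap_mask Logical masks per position.
#' @export
setClass("SiteTensor",
    representation(
        gene_id = "character",
        chrom = "character",
        strand = "character",
        start = "integer",
        n_pos = "integer",
        coverage = "matrix",
        events = "data.frame",
        lib_names = "character",
        lib_roles = "character",
        snp_mask = "logical",
        mirna_mask = "logical",
        overlap_mask = "logical"
    )
)

setValidity("SiteTensor", function(object) {
    msg <- character()
    if (nrow(object@coverage) != object@n_pos)
        msg <- c(msg, "coverage must have n_pos rows")
    if (ncol(object@coverage) != length(object@lib_names))
        msg <- c(msg, "coverage must have one column per library")
    if (length(object@lib_roles) != length(object@lib_names))
        msg <- c(msg, "lib_roles must match lib_names in length")
    if (!all(object@lib_roles %in% c("CLIP", "background")))
        msg <- c(msg, "lib_roles must be 'CLIP' or 'background'")
    if (any(object@coverage < 0))
        msg <- c(msg, "coverage must be non-negative")
    for (m in c("snp_mask", "mirna_mask", "overlap_mask"))
        if (length(slot(object, m)) != object@n_pos)
            msg <- c(msg, sprintf("%s must have length n_pos", m))
    ev <- object@events
    if (nrow(ev)) {
        if (!all(c("pos", "lib", "cat", "count") %in% names(ev)))
            msg <- c(msg, "events needs columns pos, lib, cat, count")
        else {
            if (any(ev$pos < 1L | ev$pos > object@n_pos))
                msg <- c(msg, "event positions out of range")
            if (any(ev$cat < 1L | ev$cat > .N_EVENT_CATEGORIES))
                msg <- c(msg, "event categories out of range")
            if (any(ev$count < 0))
                msg <- c(msg, "event counts must be non-negative")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn SiteTensor Show a compact summary.
#' @param object A \code{SiteTensor}.
#' @export
setMethod("show", "SiteTensor", function(object) {
    cat(sprintf(
        "SiteTensor for gene %s (%s:%d-%d, %s)\n",
        object@gene_id, object@chrom, object@start,
        object@start + object@n_pos - 1L, object@strand))
    cat(sprintf("  %d positions x %d libraries (%s)\n",
        object@n_pos, length(object@lib_names),
        paste(object@lib_roles, collapse = ", ")))
    cat(sprintf("  total coverage %d; %d event records; %d SNP-masked\n",
        sum(object@coverage), nrow(object@events), sum(object@snp_mask)))
})

#' CoverageGLM: fitted negative-binomial GLM parameters
#'
#' Parameters of the coverage model: per-library log size factors,
#' per-gene expression coefficients, the shared peak-enrichment
#' coefficient (constrained non-negative), the background-abundance
#' intercept and a single genome-wide overdispersion \code{c} giving
#' variance \code{mu + c * mu^2}.
#'
#' @slot beta0 Background (no-coverage state) intercept.
#' @slot beta_gene Named numeric, one coefficient per gene.
#' @slot beta_enrich Non-negative enrichment coefficient.
#' @slot libsize Named numeric, per-library log size factor.
#' @slot dispersion Overdispersion c >= 0.
#' @slot converged Logical fit diagnostic.
#' @export
setClass("CoverageGLM",
    representation(
        beta0 = "numeric",
        beta_gene = "numeric",
        beta_enrich = "numeric",
        libsize = "numeric",
        dispersion = "numeric",
        converged = "logical"
    ),
    prototype(converged = TRUE)
)

setValidity("CoverageGLM", function(object) {
    msg <- character()
    if (length(object@beta_enrich) != 1L || object@beta_enrich < 0)
        msg <- c(msg, "beta_enrich must be a single non-negative value")
    if (length(object@dispersion) != 1L || object@dispersion < 0)
        msg <- c(msg, "dispersion must be a single non-negative value")
    if (any(!is.finite(object@libsize)))
        msg <- c(msg, "libsize must be finite")
    if (length(msg)) msg else TRUE
})

#' @describeIn CoverageGLM Show a compact summary.
#' @param object A \code{CoverageGLM}.
#' @export
setMethod("show", "CoverageGLM", function(object) {
    cat(sprintf(
        "CoverageGLM: %d genes, beta0 = %.3f, enrichment = %.3f, c = %.4f\n",
        length(object@beta_gene), object@beta0, object@beta_enrich,
        object@dispersion))
    cat(sprintf("  library log sizes: %s\n",
        paste(sprintf("%s=%.2f", names(object@libsize), object@libsize),
            collapse = ", ")))
})

#' EventMixture: Dirichlet-multinomial mixture over event vectors
#'
#' A K-component mixture in which each component draws a latent event
#' rate vector q from a Dirichlet with concentration \code{alphas[k, ]}
#' and the per-replicate event count vectors at a position are
#' multinomial draws sharing that q.
#'
#' @slot model_class \code{"peak"} or \code{"background"}.
#' @slot weights Mixture weights on the simplex, length K.
#' @slot alphas K x (M+1) matrix of positive Dirichlet concentrations.
#' @export
setClass("EventMixture",
    representation(
        model_class = "character",
        weights = "numeric",
        alphas = "matrix"
    )
)

setValidity("EventMixture", function(object) {
    msg <- character()
    if (!object@model_class %in% c("peak", "background"))
        msg <- c(msg, "model_class must be 'peak' or 'background'")
    if (abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "weights must sum to 1")
    if (any(object@weights < 0))
        msg <- c(msg, "weights must be non-negative")
    if (nrow(object@alphas) != length(object@weights))
        msg <- c(msg, "alphas must have one row per mixture component")
    if (ncol(object@alphas) < 2L)
        msg <- c(msg, "alphas must have at least 2 category columns")
    if (any(object@alphas <= 0))
        msg <- c(msg, "alpha entries must be positive")
    if (length(msg)) msg else TRUE
})

#' @describeIn EventMixture Show a compact summary.
#' @param object An \code{EventMixture}.
#' @export
setMethod("show", "EventMixture", function(object) {
    cat(sprintf("EventMixture (%s): K = %d components\n",
        object@model_class, length(object@weights)))
    mn <- colSums(object@weights * object@alphas /
        rowSums(object@alphas))
    if (length(mn) == .N_EVENT_CATEGORIES + 1L) {
        top <- head(order(mn[-length(mn)], decreasing = TRUE), 3L)
        cat(sprintf("  top event rates: %s\n",
            paste(sprintf("%s=%.3g", eventCategories()[top], mn[top]),
                collapse = ", ")))
    }
})

#' TransitionModel: coverage-dependent transition parameters
#'
#' The probability of remaining in the current state between adjacent
#' positions is \code{plogis(w0 + w1 * log1p(total coverage))}; leaving
#' probability is split uniformly over the other three states.
#'
#' @slot w0,w1 Logistic intercept and slope.
#' @export
setClass("TransitionModel",
    representation(w0 = "numeric", w1 = "numeric"),
    prototype(w0 = 2, w1 = 0.5)
)

#' @describeIn TransitionModel Show a compact summary.
#' @param object A \code{TransitionModel}.
#' @export
setMethod("show", "TransitionModel", function(object) {
    cat(sprintf(
        "TransitionModel: stay prob = plogis(%.3f + %.3f * log1p(cov))\n",
        object@w0, object@w1))
})

#' ClipModel: the full fitted model
#'
#' Bundles the fitted coverage GLM, the peak and background
#' Dirichlet-multinomial event mixtures and the transition model,
#' together with the EM log-evidence trace.
#'
#' @slot glm A [CoverageGLM-class].
#' @slot dmm_peak,dmm_background [EventMixture-class] objects.
#' @slot transitions A [TransitionModel-class].
#' @slot logevidence Total log-evidence per outer EM iteration.
#' @slot n_iter Number of outer EM iterations run.
#' @export
setClass("ClipModel",
    representation(
        glm = "CoverageGLM",
        dmm_peak = "EventMixture",
        dmm_background = "EventMixture",
        transitions = "TransitionModel",
        logevidence = "numeric",
        n_iter = "integer"
    )
)

#' @describeIn ClipModel Show a compact summary.
#' @param object A \code{ClipModel}.
#' @export
setMethod("show", "ClipModel", function(object) {
    cat(sprintf("ClipModel: %d EM iterations\n", object@n_iter))
    if (length(object@logevidence))
        cat(sprintf("  final log-evidence: %.2f\n",
            tail(object@logevidence, 1)))
    show(object@glm)
    show(object@transitions)
})

# ---- accessors ------------------------------------------------------

#' @rdname SiteTensor-class
#' @aliases geneId
#' @param x A \code{SiteTensor}.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname SiteTensor-class
#' @export
setMethod("geneId", "SiteTensor", function(x) x@gene_id)

#' @rdname SiteTensor-class
#' @aliases libRoles
#' @export
setGeneric("libRoles", function(x) standardGeneric("libRoles"))

#' @rdname SiteTensor-class
#' @export
setMethod("libRoles", "SiteTensor", function(x) {
    setNames(x@lib_roles, x@lib_names)
})

#' @rdname SiteTensor-class
#' @aliases siteCoverage
#' @param role Optional role filter, \code{"CLIP"} or
#'   \code{"background"}.
#' @export
setGeneric("siteCoverage", function(x, role = NULL)
    standardGeneric("siteCoverage"))

#' @rdname SiteTensor-class
#' @export
setMethod("siteCoverage", "SiteTensor", function(x, role = NULL) {
    if (is.null(role)) return(x@coverage)
    x@coverage[, x@lib_roles == role, drop = FALSE]
})

#' @rdname CoverageGLM-class
#' @aliases geneCoefficients
#' @param x A \code{CoverageGLM}.
#' @export
setGeneric("geneCoefficients", function(x)
    standardGeneric("geneCoefficients"))

#' @rdname CoverageGLM-class
#' @export
setMethod("geneCoefficients", "CoverageGLM", function(x) x@beta_gene)

#' @rdname ClipModel-class
#' @aliases coverageModel
#' @param x A \code{ClipModel}.
#' @export
setGeneric("coverageModel", function(x) standardGeneric("coverageModel"))

#' @rdname ClipModel-class
#' @export
setMethod("coverageModel", "ClipModel", function(x) x@glm)

#' @rdname ClipModel-class
#' @aliases eventModel
#' @param class Which mixture: \code{"peak"} or \code{"background"}.
#' @export
setGeneric("eventModel", function(x, class = c("peak", "background"))
    standardGeneric("eventModel"))

#' @rdname ClipModel-class
#' @export
setMethod("eventModel", "ClipModel", function(x,
        class = c("peak", "background")) {
    class <- match.arg(class)
    if (class == "peak") x@dmm_peak else x@dmm_background
})

#' Pooled event-count matrix for a set of libraries
#'
#' Builds the dense (M+1)-column event count matrix for the requested
#' libraries of a [SiteTensor-class], pooled across those libraries.
#' The last column is the "no event" slot, coverage minus the event
#' total.  SNP-masked positions contribute coverage but no events, so
#' their rows are all zero except the last slot.
#'
#' @param tensor A \code{SiteTensor}.
#' @param role Pool libraries with this role (\code{"CLIP"} or
#'   \code{"background"}).
#' @param positions Optional integer vector of local positions
#'   (default: all).
#' @return Integer matrix, \code{length(positions)} x (M+1).
#' @export
pooledEvents <- function(tensor, role = "CLIP", positions = NULL) {
    if (is.null(positions)) positions <- seq_len(tensor@n_pos)
    libs <- which(tensor@lib_roles == role)
    M <- .N_EVENT_CATEGORIES
    Y <- matrix(0L, length(positions), M + 1L)
    colnames(Y) <- c(eventCategories(), "none")
    covpool <- as.integer(round(rowSums(
        tensor@coverage[positions, libs, drop = FALSE])))
    ev <- tensor@events
    if (nrow(ev)) {
        ev <- ev[ev$lib %in% libs, , drop = FALSE]
        keep <- match(ev$pos, positions)
        ok <- !is.na(keep)
        if (any(ok)) {
            idx <- cbind(keep[ok], ev$cat[ok])
            agg <- rowsum(ev$count[ok],
                group = (idx[, 1] - 1L) * (M + 1L) + idx[, 2])
            flat <- as.integer(rownames(agg))
            Y[cbind((flat - 1L) %/% (M + 1L) + 1L,
                    (flat - 1L) %% (M + 1L) + 1L)] <- agg[, 1]
        }
    }
    # SNP-masked positions carry no events at all
    masked <- tensor@snp_mask[positions]
    if (any(masked)) Y[masked, seq_len(M)] <- 0L
    Y[, M + 1L] <- pmax(covpool - rowSums(Y[, seq_len(M), drop = FALSE]),
        0L)
    if (any(masked)) Y[masked, M + 1L] <- covpool[masked]
    Y
}
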