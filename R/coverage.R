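#' Per-library log size factors
#'
#' For each library, the log of the median over genes of the gene's
#' mean per-position coverage; genes with zero coverage in that library
#' are excluded from the median.
#'
#' @param tensors List of [SiteTensor-class].
#' @return Named numeric vector of log size factors.
#' @export
estimateLibrarySizes <- function(tensors) {
    lib_names <- tensors[[1]]@lib_names
    means <- vapply(tensors, function(t) colSums(t@coverage) / t@n_pos,
        numeric(length(lib_names)))
    if (length(lib_names) == 1L) means <- matrix(means, nrow = 1L)
    ls <- vapply(seq_along(lib_names), function(w) {
        m <- means[w, ]
        m <- m[m > 0]
        if (!length(m))
            stop("library ", lib_names[w],
                 " has zero coverage in every gene")
        log(median(m))
    }, numeric(1))
    setNames(ls, lib_names)
}

#' State-dependent log mean coverage
#'
#' The linear predictor of the coverage GLM for a given library role
#' and hidden state.  For a CLIP library the peak state adds the
#' enrichment coefficient and B1 subtracts it; for a background
#' library the signs are mirrored.  The no-coverage state N uses the
#' background intercept for both roles.
#'
#' @param glm A [CoverageGLM-class].
#' @param gene_id Gene identifier(s) (vectorized).
#' @param lib Library name (must be in \code{glm@libsize}).
#' @param role \code{"CLIP"} or \code{"background"}.
#' @param state One of \code{"P"}, \code{"B1"}, \code{"B2"},
#'   \code{"N"}.
#' @return Numeric log mean(s).
#' @export
stateLogMean <- function(glm, gene_id, lib, role, state) {
    l <- glm@libsize[[lib]]
    if (!state %in% .STATE_NAMES) stop("unknown state: ", state)
    if (state == "N") return(rep(l + glm@beta0, length(gene_id)))
    bg <- glm@beta_gene[gene_id]
    sgn <- switch(state, P = 1, B1 = -1, B2 = 0)
    if (role == "background") sgn <- -sgn
    unname(l + bg + sgn * glm@beta_enrich)
}

#' Negative-binomial log-likelihood with quadratic mean-variance
#'
#' Log probability of a count under a negative binomial parameterized
#' by its mean and the overdispersion \code{c} of the relationship
#' \eqn{\sigma^2(\mu) = \mu + c\mu^2}; \code{c = 0} is the Poisson
#' limit.
#'
#' @param x Count(s).
#' @param mu Positive mean(s).
#' @param c Overdispersion, \code{c >= 0}.
#' @return Log-likelihood value(s).
#' @export
nbLogLik <- function(x, mu, c) {
    if (any(mu <= 0)) stop("mu must be positive")
    if (c < 0) stop("c must be non-negative")
    if (c == 0) dpois(x, lambda = mu, log = TRUE)
    else dnbinom(x, size = 1 / c, mu = mu, log = TRUE)
}

# ---- GLM fitting ----------------------------------------------------

# Aggregate (gene, library, coverage value) rows with per-state summed
# posterior weights.  Zero-total-coverage positions are downweighted so
# they contribute at most `zero_cap` times the covered-position count.
.aggregateGlmData <- function(tensors, posteriors, zero_cap = 10) {
    n_lib <- length(tensors[[1]]@lib_names)
    rows <- vector("list", length(tensors) * n_lib)
    ri <- 0L
    n_cov <- sum(vapply(tensors, function(t)
        sum(rowSums(t@coverage) > 0), numeric(1)))
    n_zero <- sum(vapply(tensors, function(t) t@n_pos, numeric(1))) -
        n_cov
    zw <- if (n_zero > zero_cap * n_cov && n_cov > 0)
        zero_cap * n_cov / n_zero else 1
    for (g in seq_along(tensors)) {
        t <- tensors[[g]]
        post <- posteriors[[g]]
        w_pos <- ifelse(rowSums(t@coverage) > 0, 1, zw)
        pw <- post * w_pos
        for (w in seq_len(n_lib)) {
            x <- t@coverage[, w]
            agg <- rowsum(pw, group = x)
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
                gene = g, lib = w, x = as.numeric(rownames(agg)),
                wP = agg[, 1], wB1 = agg[, 2], wB2 = agg[, 3],
                wN = agg[, 4])
        }
    }
    do.call(rbind, rows[seq_len(ri)])
}

#' Fit the negative-binomial coverage GLM
#'
#' Maximizes the posterior-weighted NB likelihood of coverage in all
#' libraries by alternating sparse IRLS updates of the coefficients
#' with one-dimensional maximum-likelihood estimation of the
#' overdispersion.  Observations are additionally weighted by the
#' inverse of their state's total posterior mass so every state is fit
#' equally well, and the enrichment coefficient is constrained
#' non-negative.  The normal-equations system is sparse (one indicator
#' column per gene plus intercept and enrichment columns), so solving
#' it scales to genome-sized gene sets.
#'
#' @param tensors List of [SiteTensor-class].
#' @param posteriors List (parallel to \code{tensors}) of
#'   positions-by-4 state posterior matrices (columns P, B1, B2, N).
#' @param libsize Optional precomputed log size factors; default
#'   [estimateLibrarySizes()].
#' @param init Optional [CoverageGLM-class] warm start.
#' @param tol IRLS convergence tolerance on max absolute coefficient
#'   change (default 1e-4).
#' @param max_iter Maximum IRLS iterations per alternation (default
#'   50).
#' @param n_alternations Number of beta/dispersion alternations
#'   (default 5).
#' @return A [CoverageGLM-class].
#' @export
fitCoverageGLM <- function(tensors, posteriors, libsize = NULL,
                           init = NULL, tol = 1e-4, max_iter = 50L,
                           n_alternations = 5L) {
    if (is.null(libsize)) libsize <- estimateLibrarySizes(tensors)
    roles <- tensors[[1]]@lib_roles
    gene_ids <- vapply(tensors, geneId, character(1))
    G <- length(tensors)
    dat <- .aggregateGlmData(tensors, posteriors)

    # state mass weights: inverse total posterior mass per state
    mass <- colSums(dat[, c("wP", "wB1", "wB2", "wN")])
    state_w <- 1 / pmax(mass, 1)

    # expand to one row per (gene, lib, x, state)
    n0 <- nrow(dat)
    states <- rep(seq_len(4L), each = n0)
    gene <- rep(dat$gene, 4L)
    lib <- rep(dat$lib, 4L)
    x <- rep(dat$x, 4L)
    w <- c(dat$wP, dat$wB1, dat$wB2, dat$wN) * state_w[states]
    keep <- w > 0
    states <- states[keep]; gene <- gene[keep]; lib <- lib[keep]
    x <- x[keep]; w <- w[keep]
    offset <- libsize[lib]

    # sparse design: col 1 = beta0 (state N), cols 2..G+1 = genes,
    # col G+2 = enrichment with sign by (role, state)
    isN <- states == 4L
    sgn <- ifelse(states == 1L, 1, ifelse(states == 2L, -1, 0))
    sgn <- ifelse(roles[lib] == "background", -sgn, sgn)
    i_idx <- c(which(isN), which(!isN),
        which(!isN & sgn != 0))
    j_idx <- c(rep(1L, sum(isN)), gene[!isN] + 1L,
        rep(G + 2L, sum(!isN & sgn != 0)))
    x_val <- c(rep(1, sum(isN)), rep(1, sum(!isN)),
        sgn[!isN & sgn != 0])
    X <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x_val,
        dims = c(length(x), G + 2L))

    # initial coefficients
    if (!is.null(init)) {
        beta <- c(init@beta0, unname(init@beta_gene[gene_ids]),
            init@beta_enrich)
        cdisp <- init@dispersion
    } else {
        gmean <- vapply(tensors, function(t)
            mean(rowSums(t@coverage)) / max(length(roles), 1), numeric(1))
        beta <- c(-2, log(pmax(gmean, 1e-3)) - mean(libsize), 0.5)
        cdisp <- 0.1
    }
    beta <- pmin(pmax(beta, -30), 30)

    obj <- function(beta, cdisp) {
        mu <- pmax(exp(pmin(offset + as.numeric(X %*% beta), 30)), 1e-10)
        sum(w * nbLogLik(x, mu, cdisp))
    }
    converged <- TRUE
    for (alt in seq_len(n_alternations)) {
        cur <- obj(beta, cdisp)
        for (it in seq_len(max_iter)) {
            eta <- offset + as.numeric(X %*% beta)
            mu <- pmax(exp(pmin(eta, 30)), 1e-10)
            W <- w * mu / (1 + cdisp * mu)
            z <- (eta - offset) + (x - mu) / mu
            XtW <- Matrix::t(X * W)
            A <- XtW %*% X + Matrix::Diagonal(G + 2L, 1e-8)
            b <- as.numeric(XtW %*% z)
            beta_new <- tryCatch(
                as.numeric(Matrix::solve(A, b)),
                error = function(e) beta)
            beta_new <- pmin(pmax(beta_new, -30), 30)
            beta_new[G + 2L] <- max(beta_new[G + 2L], 0)
            # step-halving keeps the weighted log-likelihood monotone
            step <- 1
            repeat {
                cand <- beta + step * (beta_new - beta)
                cand[G + 2L] <- max(cand[G + 2L], 0)
                val <- obj(cand, cdisp)
                if (val >= cur - 1e-9 || step < 1e-4) break
                step <- step / 2
            }
            delta <- max(abs(cand - beta))
            beta <- cand
            cur <- max(val, cur)
            if (delta < tol) break
        }
        if (it == max_iter) converged <- FALSE
        # 1-D MLE of the overdispersion given the means
        mu <- pmax(exp(pmin(offset + as.numeric(X %*% beta), 30)), 1e-10)
        oc <- optimize(function(lc) {
            sum(w * dnbinom(x, size = exp(-lc), mu = mu, log = TRUE))
        }, interval = log(c(1e-6, 1e3)), maximum = TRUE)
        pois_ll <- sum(w * dpois(x, lambda = mu, log = TRUE))
        cdisp <- if (pois_ll >= oc$objective) 0 else exp(oc$maximum)
    }
    methods::new("CoverageGLM",
        beta0 = beta[1L],
        beta_gene = setNames(beta[seq_len(G) + 1L], gene_ids),
        beta_enrich = beta[G + 2L],
        libsize = libsize,
        dispersion = cdisp,
        converged = converged)
}

#' Emission-time adjustment of gene coefficients
#'
#' Returns a copy of the GLM in which every gene coefficient below the
#' background intercept is replaced by
#' \code{beta0 + beta_enrich + 1e-5}, so that all expressed states
#' imply a higher rate than the no-coverage state when computing
#' emissions.  The fitted parameters themselves are not modified.
#'
#' @param glm A [CoverageGLM-class].
#' @return An adjusted copy.
#' @export
adjustBetaForEmission <- function(glm) {
    low <- glm@beta_gene < glm@beta0
    if (any(low))
        glm@beta_gene[low] <- glm@beta0 + glm@beta_enrich + 1e-5
    glm
}

#' Coverage emission log-probabilities for one gene
#'
#' Per-position log probability of the observed coverage in every
#' library under each hidden state: the product over libraries of NB
#' densities with state-dependent means.
#'
#' @param tensor A [SiteTensor-class].
#' @param glm A fitted (and emission-adjusted) [CoverageGLM-class].
#' @return Numeric matrix, positions x 4 (columns P, B1, B2, N).
#' @export
coverageEmission <- function(tensor, glm) {
    n <- tensor@n_pos
    out <- matrix(0, n, 4L, dimnames = list(NULL, .STATE_NAMES))
    gid <- tensor@gene_id
    for (w in seq_along(tensor@lib_names)) {
        xw <- tensor@coverage[, w]
        lib <- tensor@lib_names[w]
        role <- tensor@lib_roles[w]
        for (s in seq_len(4L)) {
            mu <- exp(min(stateLogMean(glm, gid, lib, role,
                .STATE_NAMES[s]), 30))
            out[, s] <- out[, s] + nbLogLik(xw, max(mu, 1e-10),
                glm@dispersion)
        }
    }
    out
}
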