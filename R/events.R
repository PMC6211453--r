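#' Dirichlet-multinomial log-likelihood with replicate-shared rates
#'
#' Closed form of the integral over the latent event-rate vector q of
#' the product of per-replicate multinomial likelihoods times a
#' Dirichlet density: the product of multinomial coefficients times the
#' ratio of multivariate Beta functions
#' \eqn{B(\alpha + \sum_u Y^u) / B(\alpha)}.  All replicates at a
#' position share one latent q.
#'
#' @param Y Event counts: a vector of length \code{length(alpha)} (one
#'   replicate) or a replicates-by-categories matrix.
#' @param alpha Positive Dirichlet concentration vector.
#' @return Log-likelihood (scalar).
#' @export
dmReplicateLogLik <- function(Y, alpha) {
    if (any(alpha <= 0)) stop("alpha entries must be positive")
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
    if (ncol(Y) != length(alpha))
        stop("Y and alpha dimension mismatch")
    N <- rowSums(Y)
    log_coef <- sum(lgamma(N + 1)) - sum(lgamma(Y + 1))
    ypool <- colSums(Y)
    a0 <- sum(alpha)
    log_beta_ratio <- sum(lgamma(alpha + ypool) - lgamma(alpha)) +
        lgamma(a0) - lgamma(a0 + sum(ypool))
    log_coef + log_beta_ratio
}

# per-position x component log-likelihood matrix for pooled counts
# (multinomial coefficients omitted: they are constant in the
# component and in the state, so they cancel in responsibilities and
# in state comparisons)
.dmComponentLogLik <- function(Ypool, alphas) {
    n <- nrow(Ypool)
    K <- nrow(alphas)
    ncat <- ncol(Ypool)
    N <- base::rowSums(Ypool)
    out <- matrix(0, n, K)
    for (k in seq_len(K)) {
        a <- alphas[k, ]
        a0 <- sum(a)
        Ya <- Ypool + matrix(a, n, ncat, byrow = TRUE)
        out[, k] <- base::rowSums(lgamma(Ya)) -
            sum(lgamma(a)) + lgamma(a0) - lgamma(a0 + N)
    }
    out
}

#' Mixture emission log-probability for event vectors
#'
#' Stable log of the mixture-weighted sum of Dirichlet-multinomial
#' likelihoods, \eqn{\log \sum_k \mu_k \exp(\ell_k(Y))}.
#'
#' @param Y Event counts for one position: vector or
#'   replicates-by-categories matrix.
#' @param mixture An [EventMixture-class], or a list with elements
#'   \code{weights} and \code{alphas} (K x categories matrix).
#' @return Log emission probability (scalar).
#' @export
dmmEmission <- function(Y, mixture) {
    if (is(mixture, "EventMixture"))
        mixture <- list(weights = mixture@weights,
            alphas = mixture@alphas)
    lls <- vapply(seq_along(mixture$weights), function(k)
        dmReplicateLogLik(Y, mixture$alphas[k, ]), numeric(1))
    .logSumExp(log(mixture$weights) + lls)
}

# vectorized emission over pooled count rows, coefficients omitted
.dmmEmissionRows <- function(Ypool, mixture) {
    ll <- .dmComponentLogLik(Ypool, mixture$alphas)
    .rowLogSumExp(sweep(ll, 2L, log(mixture$weights), "+"))
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' Expectation-maximization over K latent event-rate classes, with
#' Dirichlet concentrations updated by a weighted fixed-point
#' iteration.  To stabilize the fit, the best of several uniform-random
#' initializations plus an optional warm start is returned.  Training
#' positions are subsampled to at most \code{max_positions} covered
#' positions.
#'
#' @param Y Pooled event-count matrix, positions x categories (last
#'   column the "no event" slot).
#' @param model_class \code{"peak"} or \code{"background"}.
#' @param K Number of mixture components (default 10; reduced with a
#'   warning when fewer training positions are available).
#' @param weights Optional position multiplicities.
#' @param warm_start Optional [EventMixture-class] used as an extra
#'   initialization.
#' @param n_restarts Number of random initializations (default 4).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param max_positions Subsampling cap (default 1e6).
#' @param seed Optional RNG seed for initialization and subsampling.
#' @return An [EventMixture-class].
#' @export
fitEventMixture <- function(Y, model_class = c("peak", "background"),
                            K = 10L, weights = NULL, warm_start = NULL,
                            n_restarts = 4L, max_iter = 40L,
                            tol = 1e-6, max_positions = 1e6,
                            seed = NULL) {
    model_class <- match.arg(model_class)
    if (!is.null(seed)) set.seed(seed)
    if (is.null(weights)) weights <- rep(1, nrow(Y))
    if (nrow(Y) > max_positions) {
        keep <- sample.int(nrow(Y), max_positions)
        Y <- Y[keep, , drop = FALSE]
        weights <- weights[keep]
    }
    # collapse duplicate count vectors for speed
    key <- apply(Y, 1L, paste, collapse = ",")
    agg <- rowsum(weights, group = key)
    first <- !duplicated(key)
    Yu <- Y[first, , drop = FALSE]
    wu <- agg[match(key[first], rownames(agg)), 1L]
    n_eff <- sum(wu > 0)
    if (n_eff < K) {
        warning("fewer training positions than components; reducing K")
        K <- max(1L, n_eff)
    }
    ncat <- ncol(Y)

    N <- base::rowSums(Yu)
    nu <- nrow(Yu)
    # count values per category are few: evaluate lgamma/digamma on
    # unique values only and expand by index
    ucols <- lapply(seq_len(ncat), function(j) {
        u <- sort(unique(Yu[, j]))
        list(u = u, idx = match(Yu[, j], u))
    })
    uN <- sort(unique(N))
    idxN <- match(N, uN)
    comp_loglik <- function(alphas) {
        K_ <- nrow(alphas)
        out <- matrix(0, nu, K_)
        for (k in seq_len(K_)) {
            a <- alphas[k, ]
            a0 <- sum(a)
            v <- (lgamma(a0) - lgamma(a0 + uN))[idxN]
            for (j in seq_len(ncat)) {
                lg <- lgamma(ucols[[j]]$u + a[j]) - lgamma(a[j])
                v <- v + lg[ucols[[j]]$idx]
            }
            out[, k] <- v
        }
        out
    }
    mix_loglik <- function(mix) {
        ll <- comp_loglik(mix$alphas)
        sum(wu * .rowLogSumExp(ll + matrix(log(mix$weights), nu,
            length(mix$weights), byrow = TRUE)))
    }
    run_em <- function(mix, iters) {
        prev <- -Inf
        for (it in seq_len(iters)) {
            ll <- comp_loglik(mix$alphas)
            lw <- ll + matrix(log(mix$weights), nu,
                length(mix$weights), byrow = TRUE)
            tot <- .rowLogSumExp(lw)
            loglik <- sum(wu * tot)
            wr <- exp(lw - tot) * wu
            mk <- base::colSums(wr)
            mix$weights <- pmax(mk, 1e-12) / sum(pmax(mk, 1e-12))
            # fixed-point concentration update per component
            for (k in seq_len(nrow(mix$alphas))) {
                a <- mix$alphas[k, ]
                a0 <- sum(a)
                dgN <- digamma(uN + a0) - digamma(a0)
                den <- sum(wr[, k] * dgN[idxN])
                if (!is.finite(den) || den <= 0) next
                num <- vapply(seq_len(ncat), function(j) {
                    dg <- digamma(ucols[[j]]$u + a[j]) - digamma(a[j])
                    sum(wr[, k] * dg[ucols[[j]]$idx])
                }, numeric(1))
                mix$alphas[k, ] <- pmax(a * num / den, 1e-6)
            }
            if (is.finite(prev) &&
                (loglik - prev) < tol * abs(prev) + 1e-12) break
            prev <- loglik
        }
        mix$loglik <- mix_loglik(mix)
        mix
    }

    starts <- lapply(seq_len(n_restarts), function(r) list(
        weights = rep(1 / K, K),
        alphas = matrix(runif(K * ncat, 0.5, 2), K, ncat)))
    if (!is.null(warm_start) && length(warm_start@weights) == K &&
        ncol(warm_start@alphas) == ncat)
        starts <- c(starts, list(list(weights = warm_start@weights,
            alphas = warm_start@alphas)))
    # short EM for every start, then refine the best to convergence
    fits <- lapply(starts, run_em,
        iters = max(10L, ceiling(max_iter / 3)))
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    best <- run_em(best, max_iter)
    methods::new("EventMixture", model_class = model_class,
        weights = best$weights, alphas = best$alphas)
}
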