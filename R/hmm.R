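#' Coverage-dependent transition probabilities
#'
#' The probability of remaining in the current state is a logistic
#' function of log1p(total coverage); the probability of leaving is
#' split evenly over the three other states, giving a row-stochastic
#' 4 x 4 matrix at every position.
#'
#' @param X Total coverage (scalar or vector).
#' @param params A [TransitionModel-class].
#' @return For scalar \code{X} a 4 x 4 matrix; for a vector, a
#'   4 x 4 x length(X) array.
#' @export
transitionProbs <- function(X, params) {
    f <- .stayProb(X, params)
    one <- function(fi) {
        m <- matrix((1 - fi) / 3, 4L, 4L,
            dimnames = list(.STATE_NAMES, .STATE_NAMES))
        diag(m) <- fi
        m
    }
    if (length(X) == 1L) return(one(f))
    arr <- vapply(f, one, matrix(0, 4L, 4L))
    dimnames(arr) <- list(.STATE_NAMES, .STATE_NAMES, NULL)
    arr
}

.stayProb <- function(X, params) {
    f <- stats::plogis(params@w0 + params@w1 * log1p(X))
    pmin(pmax(f, 1e-6), 1 - 1e-6)
}

#' Forward-backward pass of the non-homogeneous HMM
#'
#' @param log_emissions Positions x 4 matrix of emission
#'   log-probabilities (columns P, B1, B2, N).
#' @param coverage Total coverage per position (drives transitions).
#' @param params A [TransitionModel-class].
#' @return List with \code{gamma} (state posteriors), \code{stay}
#'   (posterior probability of self-transition between adjacent
#'   positions) and \code{logZ} (log-evidence).
#' @export
forwardBackward <- function(log_emissions, coverage, params) {
    bad <- which(!apply(log_emissions, 1L, function(r)
        any(is.finite(r))))
    if (length(bad))
        stop("all emissions are -Inf at position ", bad[1])
    f <- .stayProb(coverage[-length(coverage)], params)
    res <- .fb_nhmm(log_emissions, f)
    colnames(res$gamma) <- .STATE_NAMES
    res
}

#' Viterbi decoding of the non-homogeneous HMM
#'
#' @inheritParams forwardBackward
#' @param peak_penalty Additive log-penalty applied to the peak state
#'   at decode time (e.g. -5 for eCLIP peak cores; default 0).
#' @return Integer state path (1 = P, 2 = B1, 3 = B2, 4 = N).
#' @export
viterbiPath <- function(log_emissions, coverage, params,
                        peak_penalty = 0) {
    bad <- which(!apply(log_emissions, 1L, function(r)
        any(is.finite(r))))
    if (length(bad))
        stop("all emissions are -Inf at position ", bad[1])
    f <- .stayProb(coverage[-length(coverage)], params)
    as.integer(.viterbi_nhmm(log_emissions, f, peak_penalty))
}

#' Fit the transition logistic by stochastic gradient descent
#'
#' Maximizes the expected complete-data transition log-likelihood
#' \eqn{\sum_i d_i \log f(X_i) + (1 - d_i)\log((1 - f(X_i))/3)} where
#' \eqn{d_i} is the posterior self-transition mass between positions i
#' and i+1.  Mini-batch SGD with a decaying step over a fixed number of
#' epochs; an epoch that decreases the full-batch objective is rolled
#' back with a halved step, so the objective is non-decreasing across
#' accepted epochs.
#'
#' @param stay Numeric vector of posterior self-transition
#'   probabilities.
#' @param coverage Total coverage at the left position of each pair.
#' @param init A [TransitionModel-class] starting point.
#' @param epochs,batch_size,lr SGD schedule.
#' @param seed Optional RNG seed for batch shuffling.
#' @return A fitted [TransitionModel-class].
#' @export
fitTransitionParams <- function(stay, coverage, init = NULL,
                                epochs = 40L, batch_size = 256L,
                                lr = 0.5, seed = NULL) {
    if (is.null(init)) init <- methods::new("TransitionModel")
    if (!is.null(seed)) set.seed(seed)
    d <- pmin(pmax(stay, 0), 1)
    t <- log1p(coverage)
    if (length(d) < 2L || stats::sd(d) < 1e-10) {
        warning("degenerate pair-marginals; returning prior transition",
            " parameters")
        return(init)
    }
    # centre the covariate so intercept and slope decorrelate
    tm <- mean(t)
    tc <- t - tm
    w <- c(init@w0 + init@w1 * tm, init@w1)
    objective <- function(w) {
        f <- pmin(pmax(stats::plogis(w[1] + w[2] * tc), 1e-12),
            1 - 1e-12)
        sum(d * log(f) + (1 - d) * log((1 - f) / 3))
    }
    n <- length(d)
    cur <- objective(w)
    for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        step <- lr / (1 + 0.2 * (ep - 1))
        w_old <- w
        for (b in seq(1L, n, by = batch_size)) {
            idx <- ord[b:min(b + batch_size - 1L, n)]
            f <- stats::plogis(w[1] + w[2] * tc[idx])
            g <- d[idx] - f
            w <- w + step * c(mean(g), mean(g * tc[idx]))
        }
        val <- objective(w)
        if (val < cur) {
            w <- w_old
            lr <- lr / 2
        } else cur <- val
    }
    methods::new("TransitionModel", w0 = w[1] - w[2] * tm, w1 = w[2])
}

# ---- emission assembly ---------------------------------------------

# mixture emissions for possibly repeated rows, computed on unique rows
.dmmRowsUnique <- function(Y, mixture) {
    if (is(mixture, "EventMixture"))
        mixture <- list(weights = mixture@weights,
            alphas = mixture@alphas)
    key <- apply(Y, 1L, paste, collapse = ",")
    first <- !duplicated(key)
    vals <- .dmmEmissionRows(Y[first, , drop = FALSE], mixture)
    vals[match(key, key[first])]
}

# Precomputed pooled-event structure for one gene and library role.
# Positions split into those with event records (small dense matrix,
# deduplicated) and pure "no event" positions whose emission depends
# on the pooled coverage N only; SNP-masked positions are excluded
# (their event term is 0 for every state).
.eventCache <- function(tensor, role) {
    libs <- which(tensor@lib_roles == role)
    if (!length(libs)) return(NULL)
    n <- tensor@n_pos
    M <- .N_EVENT_CATEGORIES
    covpool <- as.integer(rowSums(
        tensor@coverage[, libs, drop = FALSE]))
    ev <- tensor@events
    ev <- ev[ev$lib %in% libs & !tensor@snp_mask[ev$pos], ,
        drop = FALSE]
    ev_pos <- sort(unique(ev$pos))
    Yu <- NULL; idx_ev <- integer()
    if (length(ev_pos)) {
        Ye <- matrix(0L, length(ev_pos), M + 1L)
        r <- match(ev$pos, ev_pos)
        agg <- rowsum(ev$count, group = (r - 1L) * (M + 1L) + ev$cat)
        flat <- as.integer(rownames(agg))
        Ye[cbind((flat - 1L) %/% (M + 1L) + 1L,
                 (flat - 1L) %% (M + 1L) + 1L)] <- agg[, 1L]
        Ye[, M + 1L] <- pmax(covpool[ev_pos] -
            rowSums(Ye[, seq_len(M), drop = FALSE]), 0L)
        key <- apply(Ye, 1L, paste, collapse = ",")
        first <- !duplicated(key)
        Yu <- Ye[first, , drop = FALSE]
        idx_ev <- match(key, key[first])
    }
    nonev <- setdiff(which(!tensor@snp_mask), ev_pos)
    uniqN <- sort(unique(covpool[nonev]))
    list(n_pos = n, ev_pos = ev_pos, Yu = Yu, idx_ev = idx_ev,
         nonev = nonev, uniqN = uniqN,
         idxN = match(covpool[nonev], uniqN), ncat = M + 1L)
}

.dmmEmissionCached <- function(cache, mixture) {
    if (is(mixture, "EventMixture"))
        mixture <- list(weights = mixture@weights,
            alphas = mixture@alphas)
    out <- numeric(cache$n_pos)
    if (length(cache$ev_pos))
        out[cache$ev_pos] <-
            .dmmEmissionRows(cache$Yu, mixture)[cache$idx_ev]
    if (length(cache$nonev)) {
        A <- mixture$alphas
        a0 <- rowSums(A)
        al <- A[, cache$ncat]
        Nv <- cache$uniqN
        ll <- vapply(seq_len(nrow(A)), function(k)
            lgamma(a0[k]) - lgamma(a0[k] + Nv) +
                lgamma(al[k] + Nv) - lgamma(al[k]),
            numeric(length(Nv)))
        if (length(Nv) == 1L) ll <- matrix(ll, nrow = 1L)
        g <- .rowLogSumExp(sweep(ll, 2L, log(mixture$weights), "+"))
        out[cache$nonev] <- g[cache$idxN]
    }
    out
}

#' Full emission log-probability matrix for one gene
#'
#' Combines the coverage emissions with the diagnostic-event
#' emissions.  CLIP-library event vectors are scored under the peak
#' mixture in state P and under the background mixture in the other
#' states; background-library event vectors are scored under the
#' background mixture in every state.  SNP-masked positions contribute
#' no event term.
#'
#' @param tensor A [SiteTensor-class].
#' @param glm An emission-adjusted [CoverageGLM-class].
#' @param dmm_peak,dmm_background [EventMixture-class] objects.
#' @param cache Optional precomputed event cache (internal use).
#' @return Positions x 4 matrix of emission log-probabilities.
#' @export
emissionMatrix <- function(tensor, glm, dmm_peak, dmm_background,
                           cache = NULL) {
    em <- coverageEmission(tensor, glm)
    if (is.null(cache))
        cache <- list(clip = .eventCache(tensor, "CLIP"),
            bg = .eventCache(tensor, "background"))
    epk <- .dmmEmissionCached(cache$clip, dmm_peak)
    ebg <- .dmmEmissionCached(cache$clip, dmm_background)
    em[, 1L] <- em[, 1L] + epk
    em[, 2:4] <- em[, 2:4] + ebg
    if (!is.null(cache$bg))
        em <- em + .dmmEmissionCached(cache$bg, dmm_background)
    em
}

# per-position CLIP-event log-odds (peak vs background mixture); the
# summit statistic
.eventLogOdds <- function(tensor, dmm_peak, dmm_background,
                          cache = NULL) {
    if (is.null(cache)) cache <- .eventCache(tensor, "CLIP")
    .dmmEmissionCached(cache, dmm_peak) -
        .dmmEmissionCached(cache, dmm_background)
}

# ---- EM orchestration ----------------------------------------------

# crude initial hard state assignment from size-normalized coverage
.initialPosteriors <- function(tensor, libsize) {
    clip <- which(tensor@lib_roles == "CLIP")
    bg <- which(tensor@lib_roles == "background")
    sz <- exp(libsize[tensor@lib_names])
    cn <- rowSums(sweep(tensor@coverage[, clip, drop = FALSE], 2L,
        sz[clip], "/")) / length(clip)
    bn <- if (length(bg))
        rowSums(sweep(tensor@coverage[, bg, drop = FALSE], 2L,
            sz[bg], "/")) / length(bg)
    else rep(mean(cn), tensor@n_pos)
    tot <- rowSums(tensor@coverage)
    ratio <- (cn + 0.5) / (bn + 0.5)
    state <- ifelse(tot == 0, 4L,
        ifelse(ratio > 2, 1L, ifelse(ratio < 0.5, 2L, 3L)))
    post <- matrix(0.025, tensor@n_pos, 4L)
    post[cbind(seq_len(tensor@n_pos), state)] <- 0.925
    post
}

# gather pooled event vectors at selected positions over all genes
.gatherEvents <- function(tensors, position_sets, role,
                          max_positions = 1e6, seed = NULL) {
    mats <- mapply(function(t, pos) {
        if (!length(pos)) return(NULL)
        pooledEvents(t, role, pos)
    }, tensors, position_sets, SIMPLIFY = FALSE)
    Y <- do.call(rbind, mats[!vapply(mats, is.null, TRUE)])
    if (is.null(Y)) return(NULL)
    Y <- Y[rowSums(Y) > 0, , drop = FALSE]
    if (!nrow(Y)) return(NULL)
    if (nrow(Y) > max_positions) {
        if (!is.null(seed)) set.seed(seed)
        Y <- Y[sample.int(nrow(Y), max_positions), , drop = FALSE]
    }
    Y
}

# provisional peak positions before any segmentation exists: the
# top-coverage 1% of covered positions (pooled CLIP coverage)
.provisionalPeaks <- function(tensors) {
    covs <- lapply(tensors, function(t)
        rowSums(siteCoverage(t, "CLIP")))
    all_cov <- unlist(covs)
    pos_cov <- all_cov[all_cov > 0]
    if (!length(pos_cov))
        return(lapply(tensors, function(t) integer()))
    thr <- quantile(pos_cov, 0.99, names = FALSE)
    lapply(seq_along(tensors), function(g) {
        t <- tensors[[g]]
        which(covs[[g]] >= max(thr, 1) & !t@overlap_mask &
            !t@snp_mask)
    })
}

.fitBothMixtures <- function(tensors, peak_sets, K, warm_peak,
                             warm_bg, seed) {
    has_bg <- any(tensors[[1]]@lib_roles == "background")
    Yp <- .gatherEvents(tensors, peak_sets, "CLIP", seed = seed)
    if (is.null(Yp)) return(list(peak = warm_peak, background = warm_bg))
    dmm_peak <- fitEventMixture(Yp, "peak", K = K,
        warm_start = warm_peak, seed = .deriveSeed(seed, 1L))
    if (has_bg) {
        Yb <- .gatherEvents(tensors, peak_sets, "background",
            seed = seed)
    } else {
        # no background libraries: score non-peak CLIP positions as the
        # background event class
        nonpeak <- lapply(seq_along(tensors), function(g) {
            t <- tensors[[g]]
            cov <- rowSums(siteCoverage(t, "CLIP"))
            setdiff(which(cov > 0 & !t@overlap_mask & !t@snp_mask),
                peak_sets[[g]])
        })
        Yb <- .gatherEvents(tensors, nonpeak, "CLIP", seed = seed)
    }
    dmm_bg <- if (is.null(Yb)) warm_bg else
        fitEventMixture(Yb, "background", K = K, warm_start = warm_bg,
            seed = .deriveSeed(seed, 2L))
    if (is.null(dmm_bg)) dmm_bg <- dmm_peak
    list(peak = dmm_peak, background = dmm_bg)
}

#' Fit the full CLIP peak-calling model by EM
#'
#' Iterates between the E-step (forward-backward over every gene with
#' the current emissions and transitions) and M-steps for the coverage
#' GLM, the two Dirichlet-multinomial event mixtures (peak mixture on
#' CLIP-library events at current peak positions, background mixture on
#' background-library events at the same positions) and the transition
#' logistic.  Runs at least \code{min_iter} and at most \code{max_iter}
#' outer iterations, stopping early once the relative improvement of
#' the total log-evidence falls below \code{tol}.
#'
#' @param tensors Named list of [SiteTensor-class], one per gene.
#' @param k_components Mixture components for the event model
#'   (default 10).
#' @param min_iter,max_iter Outer EM iteration bounds (defaults 5 and
#'   10).
#' @param tol Relative log-evidence improvement threshold for early
#'   stopping (default 1e-3).
#' @param seed RNG seed for all stochastic fitting steps.
#' @param verbose Print per-iteration progress.
#' @return A [ClipModel-class].
#' @export
emFit <- function(tensors, k_components = 10L, min_iter = 5L,
                  max_iter = 10L, tol = 1e-3, seed = 1L,
                  verbose = FALSE) {
    if (!any(vapply(tensors, function(t)
        any(t@lib_roles == "CLIP"), TRUE)))
        stop("at least one CLIP library is required")
    libsize <- estimateLibrarySizes(tensors)

    posts <- lapply(tensors, .initialPosteriors, libsize = libsize)
    glm <- fitCoverageGLM(tensors, posts, libsize = libsize)
    prov <- .provisionalPeaks(tensors)
    mix <- .fitBothMixtures(tensors, prov, k_components, NULL, NULL,
        .deriveSeed(seed, 100L))
    trans <- methods::new("TransitionModel")
    caches <- lapply(tensors, function(t)
        list(clip = .eventCache(t, "CLIP"),
             bg = .eventCache(t, "background")))

    trace <- numeric()
    it <- 0L
    repeat {
        it <- it + 1L
        glm_adj <- adjustBetaForEmission(glm)
        gammas <- vector("list", length(tensors))
        stays <- vector("list", length(tensors))
        covs <- vector("list", length(tensors))
        peak_sets <- vector("list", length(tensors))
        logZ <- 0
        for (g in seq_along(tensors)) {
            t <- tensors[[g]]
            em <- emissionMatrix(t, glm_adj, mix$peak, mix$background,
                cache = caches[[g]])
            cov <- rowSums(t@coverage)
            fb <- tryCatch(forwardBackward(em, cov, trans),
                error = function(e) stop("gene ", geneId(t),
                    ", iteration ", it, ": ", conditionMessage(e)))
            gammas[[g]] <- fb$gamma
            stays[[g]] <- fb$stay
            covs[[g]] <- cov
            logZ <- logZ + fb$logZ
            amax <- max.col(fb$gamma, ties.method = "first")
            peak_sets[[g]] <- which(amax == 1L & cov > 0 &
                !t@overlap_mask & !t@snp_mask)
        }
        trace <- c(trace, logZ)
        if (verbose)
            message(sprintf("EM iteration %d: log-evidence %.2f", it,
                logZ))
        done <- it >= max_iter ||
            (it > min_iter &&
             abs(trace[it] - trace[it - 1L]) <
                 tol * abs(trace[it - 1L]))
        if (done) break

        glm <- fitCoverageGLM(tensors, gammas, libsize = libsize,
            init = glm)
        if (!sum(lengths(peak_sets))) peak_sets <- prov
        mix <- .fitBothMixtures(tensors, peak_sets, k_components,
            mix$peak, mix$background, .deriveSeed(seed, it))
        trans <- fitTransitionParams(unlist(stays),
            unlist(lapply(covs, function(x) x[-length(x)])),
            init = trans, seed = .deriveSeed(seed, 1000L + it))
    }
    methods::new("ClipModel", glm = glm, dmm_peak = mix$peak,
        dmm_background = mix$background, transitions = trans,
        logevidence = trace, n_iter = it)
}
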