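# Independent reference implementations used as test oracles.

# brute-force HMM evidence and best path by enumerating all 4^n paths
enumerate_nhmm <- function(log_emissions, f) {
    n <- nrow(log_emissions)
    S <- ncol(log_emissions)
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
    lp <- numeric(nrow(paths))
    for (r in seq_len(nrow(paths))) {
        p <- paths[r, ]
        v <- -log(S) + log_emissions[1L, p[1L]]
        for (i in seq_len(n - 1L)) {
            tr <- if (p[i] == p[i + 1L]) f[i] else (1 - f[i]) / 3
            v <- v + log(tr) + log_emissions[i + 1L, p[i + 1L]]
        }
        lp[r] <- v
    }
    m <- max(lp)
    list(logZ = m + log(sum(exp(lp - m))),
         best = paths[which.max(lp), ])
}

# Dirichlet-multinomial integral over the simplex by nested adaptive
# quadrature, for 3 categories (M = 2): replicates share one latent q
dm_quadrature_m2 <- function(Y, alpha) {
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
    stopifnot(ncol(Y) == 3L, length(alpha) == 3L)
    coef <- prod(apply(Y, 1L, function(y)
        exp(lgamma(sum(y) + 1) - sum(lgamma(y + 1)))))
    dir_const <- exp(lgamma(sum(alpha)) - sum(lgamma(alpha)))
    ytot <- colSums(Y)
    inner <- function(q1) {
        vapply(q1, function(a) {
            g <- function(q2) {
                q3 <- 1 - a - q2
                a^(ytot[1] + alpha[1] - 1) *
                    q2^(ytot[2] + alpha[2] - 1) *
                    q3^(ytot[3] + alpha[3] - 1)
            }
            stats::integrate(g, 0, 1 - a, rel.tol = 1e-12,
                abs.tol = 1e-300)$value
        }, numeric(1))
    }
    val <- stats::integrate(inner, 0, 1, rel.tol = 1e-10,
        abs.tol = 1e-300)$value
    log(coef) + log(dir_const) + log(val)
}

# dense-matrix IRLS for the coverage GLM, mirroring the model but with
# an explicit dense design and base solve(); used to check the sparse
# path
dense_irls_reference <- function(x, offset, gene, sgn, isN, w, G,
                                 cdisp, beta, tol = 1e-4,
                                 max_iter = 50L) {
    n <- length(x)
    X <- matrix(0, n, G + 2L)
    X[cbind(which(isN), 1L)] <- 1
    X[cbind(which(!isN), gene[!isN] + 1L)] <- 1
    X[, G + 2L] <- ifelse(isN, 0, sgn)
    obj <- function(b) {
        mu <- pmax(exp(pmin(offset + X %*% b, 30)), 1e-10)
        sum(w * dnbinom(x, size = 1 / max(cdisp, 1e-12), mu = mu,
            log = TRUE))
    }
    cur <- obj(beta)
    for (it in seq_len(max_iter)) {
        eta <- offset + as.numeric(X %*% beta)
        mu <- pmax(exp(pmin(eta, 30)), 1e-10)
        W <- w * mu / (1 + cdisp * mu)
        z <- (eta - offset) + (x - mu) / mu
        A <- crossprod(X * sqrt(W)) + diag(1e-8, G + 2L)
        b <- crossprod(X, W * z)
        beta_new <- pmin(pmax(as.numeric(solve(A, b)), -30), 30)
        beta_new[G + 2L] <- max(beta_new[G + 2L], 0)
        step <- 1
        repeat {
            cand <- beta + step * (beta_new - beta)
            cand[G + 2L] <- max(cand[G + 2L], 0)
            val <- obj(cand)
            if (val >= cur - 1e-9 || step < 1e-4) break
            step <- step / 2
        }
        delta <- max(abs(cand - beta))
        beta <- cand
        cur <- max(val, cur)
        if (delta < tol) break
    }
    beta
}
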