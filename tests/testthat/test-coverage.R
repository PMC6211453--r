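test_that("library size is the log median of per-gene mean coverage", {
    mk <- function(mean_cov, n = 10L) {
        cov <- matrix(as.integer(mean_cov), n, 1L,
            dimnames = list(NULL, "libA"))
        make_tensor(cov, roles = "CLIP")
    }
    tns <- list(mk(2L), mk(8L), mk(32L))
    expect_equal(unname(estimateLibrarySizes(tns)), log(8))
    # all genes identical: log of the common mean
    expect_equal(unname(estimateLibrarySizes(list(mk(5L), mk(5L)))),
        log(5))
    # single gene
    expect_equal(unname(estimateLibrarySizes(list(mk(7L)))), log(7))
    # zero-coverage genes are excluded from the median
    expect_equal(unname(estimateLibrarySizes(
        list(mk(0L), mk(2L), mk(8L), mk(32L)))), log(8))
    # a library with no coverage anywhere is an error
    expect_error(estimateLibrarySizes(list(mk(0L))), "zero coverage")
})

test_that("state log means follow the mirrored enrichment scheme", {
    glm <- methods::new("CoverageGLM", beta0 = -2,
        beta_gene = c(g1 = 1.5, g2 = 0.2), beta_enrich = 0.8,
        libsize = c(u = 0.4, v = -0.1), dispersion = 0.1)
    expect_equal(stateLogMean(glm, "g1", "u", "CLIP", "B2"),
        0.4 + 1.5)
    expect_equal(stateLogMean(glm, "g1", "u", "CLIP", "P"),
        0.4 + 1.5 + 0.8)
    expect_equal(stateLogMean(glm, "g1", "u", "CLIP", "N"), 0.4 - 2)
    # P - B1 = 2 * enrichment for any gene, CLIP role
    for (g in c("g1", "g2"))
        expect_equal(
            stateLogMean(glm, g, "u", "CLIP", "P") -
            stateLogMean(glm, g, "u", "CLIP", "B1"), 2 * 0.8)
    # enrichment antisymmetry: CLIP P + background P equals
    # CLIP B1 + background B1
    expect_equal(
        stateLogMean(glm, "g1", "u", "CLIP", "P") +
        stateLogMean(glm, "g1", "v", "background", "P"),
        stateLogMean(glm, "g1", "u", "CLIP", "B1") +
        stateLogMean(glm, "g1", "v", "background", "B1"))
    expect_error(stateLogMean(glm, "g1", "u", "CLIP", "Q"),
        "unknown state")
})

test_that("NB log-likelihood reduces to Poisson and normalizes", {
    grid <- expand.grid(x = c(0L, 1L, 5L, 20L, 100L),
        mu = c(0.1, 1, 5, 50))
    expect_equal(nbLogLik(grid$x, grid$mu, 0),
        dpois(grid$x, grid$mu, log = TRUE), tolerance = 1e-12)
    # normalization at (mu, c) = (5, 0.3)
    xs <- 0:2000
    expect_equal(sum(exp(nbLogLik(xs, 5, 0.3))), 1, tolerance = 1e-8)
    # mean-variance relationship via sampling at (10, 0.1)
    set.seed(42)
    draws <- rnbinom(2e5, size = 1 / 0.1, mu = 10)
    expect_equal(var(draws), 10 + 0.1 * 100, tolerance = 0.05)
    expect_error(nbLogLik(1L, 0, 0.1), "mu")
})

test_that("GLM collapses to per-gene means when all positions are B2", {
    set.seed(1)
    n <- 50L
    tns <- lapply(c(4, 9, 25), function(m) {
        cov <- matrix(rpois(n, m), n, 1L,
            dimnames = list(NULL, "u"))
        make_tensor(cov, roles = "CLIP",
            gene_id = paste0("g", m))
    })
    posts <- lapply(tns, function(t) {
        p <- matrix(0, t@n_pos, 4L); p[, 3L] <- 1; p
    })
    fit <- fitCoverageGLM(tns, posts)
    l <- fit@libsize[["u"]]
    for (t in tns) {
        expect_equal(
            unname(fit@beta_gene[geneId(t)]),
            log(mean(t@coverage)) - l, tolerance = 0.02)
    }
})

test_that("sparse IRLS equals a dense reference on a small toy", {
    set.seed(5)
    G <- 5L
    tns <- lapply(seq_len(G), function(g) {
        cov <- cbind(u = rpois(40L, 3 * g), v = rpois(40L, 2 * g))
        storage.mode(cov) <- "integer"
        make_tensor(cov, roles = c("CLIP", "background"),
            gene_id = paste0("g", g))
    })
    posts <- lapply(tns, function(t) {
        p <- matrix(runif(t@n_pos * 4L), t@n_pos, 4L)
        p / rowSums(p)
    })
    libsize <- estimateLibrarySizes(tns)
    init <- methods::new("CoverageGLM", beta0 = -1,
        beta_gene = setNames(rep(0, G), paste0("g", seq_len(G))),
        beta_enrich = 0.5, libsize = libsize, dispersion = 0.1)
    fit <- fitCoverageGLM(tns, posts, libsize = libsize, init = init,
        n_alternations = 1L)

    # reconstruct the expanded weighted observations independently
    dat <- clipHMM:::.aggregateGlmData(tns, posts)
    mass <- colSums(dat[, c("wP", "wB1", "wB2", "wN")])
    state_w <- 1 / pmax(mass, 1)
    n0 <- nrow(dat)
    states <- rep(1:4, each = n0)
    gene <- rep(dat$gene, 4L)
    lib <- rep(dat$lib, 4L)
    x <- rep(dat$x, 4L)
    w <- c(dat$wP, dat$wB1, dat$wB2, dat$wN) * state_w[states]
    keep <- w > 0
    roles <- c("CLIP", "background")
    sgn <- ifelse(states == 1L, 1, ifelse(states == 2L, -1, 0))
    sgn <- ifelse(roles[lib] == "background", -sgn, sgn)
    beta_ref <- dense_irls_reference(
        x = x[keep], offset = libsize[lib[keep]], gene = gene[keep],
        sgn = sgn[keep], isN = states[keep] == 4L, w = w[keep], G = G,
        cdisp = 0.1, beta = c(-1, rep(0, G), 0.5))
    expect_equal(unname(fit@beta_gene),
        beta_ref[seq_len(G) + 1L], tolerance = 1e-6)
    expect_equal(fit@beta0, beta_ref[1L], tolerance = 1e-6)
    expect_equal(fit@beta_enrich, beta_ref[G + 2L], tolerance = 1e-6)
})

test_that("GLM recovers parameters from data simulated by its model", {
    set.seed(11)
    G <- 50L
    n <- 80L
    l <- c(u1 = 0.5, u2 = 0.3, v1 = 0.6, v2 = 0.2)
    roles <- c("CLIP", "CLIP", "background", "background")
    beta_g <- rnorm(G, 1, 1.2)
    beta_e <- 0.9
    c_true <- 0.15
    states <- matrix(sample(1:4, G * n, replace = TRUE,
        prob = c(0.1, 0.2, 0.5, 0.2)), G, n)
    tns <- list(); posts <- list()
    for (g in seq_len(G)) {
        cov <- matrix(0L, n, 4L, dimnames = list(NULL, names(l)))
        for (w in seq_len(4L)) {
            sgn <- c(1, -1, 0, 0)[states[g, ]]
            if (roles[w] == "background") sgn <- -sgn
            eta <- l[w] + ifelse(states[g, ] == 4L, -2,
                beta_g[g] + sgn * beta_e)
            cov[, w] <- rnbinom(n, size = 1 / c_true, mu = exp(eta))
        }
        tns[[g]] <- make_tensor(cov, roles = roles,
            gene_id = sprintf("g%02d", g))
        p <- matrix(0, n, 4L)
        p[cbind(seq_len(n), states[g, ])] <- 1
        posts[[g]] <- p
    }
    fit <- fitCoverageGLM(tns, posts)
    expect_gt(cor(unname(fit@beta_gene), beta_g,
        method = "spearman"), 0.95)
    expect_lt(abs(fit@dispersion - c_true) / c_true, 0.5)
    expect_gt(fit@beta_enrich, 0)

    # gene-order invariance
    ord <- rev(seq_len(G))
    fit2 <- fitCoverageGLM(tns[ord], posts[ord])
    expect_equal(fit2@beta_gene[names(fit@beta_gene)],
        fit@beta_gene, tolerance = 1e-6)
})

test_that("emission-time coefficient adjustment floors weak genes", {
    glm <- methods::new("CoverageGLM", beta0 = -1,
        beta_gene = c(g1 = -2, g2 = 1, g3 = -1.0001),
        beta_enrich = 0.5, libsize = c(u = 0), dispersion = 0.1)
    adj <- adjustBetaForEmission(glm)
    expect_equal(unname(adj@beta_gene[["g1"]]), -1 + 0.5 + 1e-5)
    expect_equal(unname(adj@beta_gene[["g3"]]), -1 + 0.5 + 1e-5)
    expect_equal(unname(adj@beta_gene[["g2"]]), 1)
    # original untouched
    expect_equal(unname(glm@beta_gene[["g1"]]), -2)
    # genome where every gene is weak: all genes share one value
    glm2 <- glm
    glm2@beta_gene <- c(g1 = -5, g2 = -4, g3 = -3)
    adj2 <- adjustBetaForEmission(glm2)
    expect_identical(length(unique(unname(adj2@beta_gene))), 1L)
})

test_that("coverage emissions multiply across libraries", {
    glm <- methods::new("CoverageGLM", beta0 = -1,
        beta_gene = c(g1 = 1), beta_enrich = 0.7,
        libsize = c(u = 0.3, v = 0.1), dispersion = 0.2)
    cov <- cbind(u = c(9L, 0L), v = c(1L, 0L))
    t2 <- make_tensor(cov, roles = c("CLIP", "background"))
    em <- coverageEmission(t2, glm)
    # sum of the two single-library terms
    tu <- make_tensor(cov[, 1L, drop = FALSE], roles = "CLIP")
    tv <- make_tensor(cov[, 2L, drop = FALSE], roles = "background")
    glm_u <- glm; glm_u@libsize <- glm@libsize["u"]
    glm_v <- glm; glm_v@libsize <- glm@libsize["v"]
    expect_equal(em,
        coverageEmission(tu, glm_u) + coverageEmission(tv, glm_v))
    # doubling the library set with identical data doubles log p
    cov4 <- cbind(cov, cov)
    colnames(cov4) <- c("u", "v", "u2", "v2")
    t4 <- make_tensor(cov4,
        roles = c("CLIP", "background", "CLIP", "background"))
    glm4 <- glm
    glm4@libsize <- c(glm@libsize, u2 = 0.3, v2 = 0.1)
    expect_equal(coverageEmission(t4, glm4), 2 * em)
    # CLIP >> background favors the peak state over B1
    expect_gt(em[1L, "P"], em[1L, "B1"])
    expect_true(all(is.finite(em)))
})

test_that("swapping CLIP and background roles swaps P and B1", {
    glm <- methods::new("CoverageGLM", beta0 = -1,
        beta_gene = c(g1 = 1), beta_enrich = 0.7,
        libsize = c(a = 0.2, b = 0.2), dispersion = 0.1)
    cov <- cbind(a = c(5L, 2L, 0L), b = c(1L, 7L, 3L))
    t1 <- make_tensor(cov, roles = c("CLIP", "background"))
    t2 <- make_tensor(cov, roles = c("background", "CLIP"))
    e1 <- coverageEmission(t1, glm)
    e2 <- coverageEmission(t2, glm)
    expect_equal(e1[, "P"], e2[, "B1"])
    expect_equal(e1[, "B1"], e2[, "P"])
    expect_equal(e1[, "B2"], e2[, "B2"])
    expect_equal(e1[, "N"], e2[, "N"])
})
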