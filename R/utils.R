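# internal numeric helpers

# log(sum(exp(x))) along rows of a matrix, stable
.rowLogSumExp <- function(m) {
    mx <- m[, 1L]
    for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
    bad <- !is.finite(mx)
    out <- mx + log(base::rowSums(exp(m - mx)))
    if (any(bad)) out[bad] <- mx[bad]
    out
}

.logSumExp <- function(x) {
    mx <- max(x)
    if (!is.finite(mx)) return(mx)
    mx + log(sum(exp(x - mx)))
}

# derive a stream-specific 32-bit seed from a master seed
.deriveSeed <- function(seed, stream) {
    as.integer((as.numeric(seed) * 48271 + stream * 104729) %% 2147483647)
}
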