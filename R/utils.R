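# internal helpers shared across modules

# evaluate expr under a temporary seed (NULL = use current RNG state)
.withSeed <- function(seed, expr) {
    if (is.null(seed)) expr
    else withr::with_seed(as.integer(seed), expr)
}

# truncated-normal draws by quantile inversion; sd = 0 degenerates to the
# mean (which must lie inside the bounds)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    if (sd == 0) {
        if (mean < lower || mean > upper)
            stop("degenerate truncated normal: mean outside [lower, upper]")
        return(rep(mean, n))
    }
    pl <- stats::pnorm(lower, mean, sd)
    pu <- stats::pnorm(upper, mean, sd)
    if (pu - pl < 1e-12)
        stop("truncation bounds leave no probability mass")
    stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# mean of a truncated normal (closed form); used by tests as an oracle and
# by nothing on the estimation path
.truncnormMean <- function(mean, sd, lower = -Inf, upper = Inf) {
    if (sd == 0) return(mean)
    a <- (lower - mean) / sd
    b <- (upper - mean) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# shift a matrix by integer pixels, filling exposed pixels with `fill`
.shiftMatrix <- function(m, dx, dy, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    src_r <- seq_len(nrow(m)) - dx
    src_c <- seq_len(ncol(m)) - dy
    ok_r <- src_r >= 1 & src_r <= nrow(m)
    ok_c <- src_c >= 1 & src_c <= ncol(m)
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
}

.stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
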