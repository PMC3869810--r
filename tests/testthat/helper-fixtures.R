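# shared builders for the test suite

std_protocol <- function() AcquisitionProtocol()

std_model <- function(...) {
    args <- list(s_base = 100, t_onset = 10, t_peak_offset = 54,
                 amplitude = 100, shape_alpha = 3, washout_fraction = 0.6)
    over <- list(...)
    args[names(over)] <- over
    do.call(EnhancementModel, args)
}

# model curve sampled on the acquisition grid, optionally degraded
model_curve <- function(model = std_model(), protocol = std_protocol(),
                        noise_sd = 0, seed = NULL) {
    tt <- frameTimes(protocol)
    y <- enhancementSignal(model, tt)
    if (noise_sd > 0)
        y <- withr::with_seed(seed %||% 1L,
                              y + rnorm(length(y), 0, noise_sd))
    SignalTimeCurve(tt, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form enhancement integral of the model over [t_onset, t_end],
# via the incomplete-gamma representation of the gamma-variate; an
# independent oracle for the dense-grid integration in analyticParams
closed_form_pei <- function(model, t_end, pei_scale = 0.001) {
    a <- model@shape_alpha; w <- model@washout_fraction
    tp <- model@t_peak_offset
    Ig <- function(x)  # int_0^x tau^a exp(a(1-tau)) dtau
        exp(a) * gamma(a + 1) / a^(a + 1) * pgamma(a * x, a + 1)
    xe <- (t_end - model@t_onset) / tp
    stopifnot(xe > 1)
    raw <- Ig(1) + w * (Ig(xe) - Ig(1)) + (1 - w) * (xe - 1)
    model@amplitude * tp * raw * pei_scale
}
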