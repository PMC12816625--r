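# Frozen dropout-curve defaults. Calibrated once by bisection of
# calibrate_dropout_midpoint() against the closed-form expected detection
# count on the default catalogs (see the methods vignette): the single-cell
# midpoint targets a median of ~1100 detected proteins per cell on a
# 3000-protein catalog; the mini-bulk midpoint targets ~3100 detected
# proteins per 500-cell sample on a 3500-protein catalog.

#' @rdname scp_config
#' @format NULL
#' @export
SCP_DROPOUT_MIDPOINT <- 8.953

#' @rdname minibulk_config
#' @format NULL
#' @export
MINIBULK_DROPOUT_MIDPOINT <- 7.063
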