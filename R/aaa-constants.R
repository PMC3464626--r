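# family vocabulary shared across modules
FAMILY_ORDER <- c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB",
                  "nifU", "nifS", "nifV", "nifQ", "anfG", "vnfG")
ALPHA_FAMILIES <- c("nifD", "nifE")   # D-subunit-type (alpha) families
BETA_FAMILIES <- c("nifK", "nifN")    # K-subunit-type (beta) families
DEKN_FAMILIES <- c(ALPHA_FAMILIES, BETA_FAMILIES)

`%||%` <- function(a, b) if (is.null(a)) b else a
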