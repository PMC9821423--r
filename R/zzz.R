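# data.table non-standard evaluation is used throughout
#' @import data.table
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE
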