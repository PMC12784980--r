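#' @useDynLib hmmpeaks, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c("insert", "chrom", "pos"))
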