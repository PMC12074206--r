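#' @importFrom data.table as.data.table fread fwrite melt dcast setDF
#' @importFrom stats sd var rnorm runif cor pt t.test p.adjust ave setNames
#' @importFrom utils modifyList head capture.output read.csv
NULL

.datatable.aware <- TRUE
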