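#' @keywords internal
#' @importFrom data.table data.table as.data.table fread fwrite rbindlist
#'   setorderv setkeyv CJ :=
#' @importFrom stats setNames
"_PACKAGE"

# data.table is used through the :: prefix but its [ syntax must be active
.datatable.aware <- TRUE

# quiet R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".N", "m", "u", "meth", "unmeth", "m_a", "u_a", "m_b", "u_b", "ma", "ua",
  "mb", "ub", "level_a", "level_b", "delta", "p", "q", "w", "grp", "context",
  "cluster_label", "r", "level", "bin"))
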