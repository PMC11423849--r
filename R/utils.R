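## Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

log2p1 <- function(x) log2(x + 1)

#' Default follicle stage series per cell type
#'
#' The nine-stage follicle series (Types 1--7 with sub-stages 3a/3b and
#' 5a/5b) as sampled for each cell type: oocytes (OC) span all nine stages,
#' granulosa cells (GC) appear from Type 2 onward, and cumulus cells (CC)
#' only exist in antral follicles (Types 6--7). The series is configuration,
#' not a hard-coded universe: any named list of ordered stage-label vectors
#' is accepted wherever a `stage_series` argument appears.
#'
#' @return Named list of character vectors, one per cell type, each ordered
#'   from earliest to latest stage.
#' @export
#' @examples
#' default_stage_series()
default_stage_series <- function() {
  list(
    OC = c("T1", "T2", "T3a", "T3b", "T4", "T5a", "T5b", "T6", "T7"),
    GC = c("T2", "T3a", "T3b", "T4", "T5a", "T5b", "T6", "T7"),
    CC = c("T6", "T7")
  )
}

## Plain TSV I/O: tab-delimited, no quoting, UTF-8.
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#", ...)
}

write_tsv_file <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
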