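# bind a list of data-frame fragments (possibly with NULLs) into one table;
# returns NULL when nothing remains
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
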