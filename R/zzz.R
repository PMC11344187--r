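.onLoad <- function(libname, pkgname) {
  # per-replicate aggregations are small; thread spin-up costs more than it saves
  data.table::setDTthreads(1L)
  invisible(NULL)
}
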