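# Result serialization with provenance.

# FNV-1a over the formatted parameter leaves; cheap provenance fingerprint
param_hash <- function(p) {
  s <- paste(names(flatten_parameters(p)),
             vapply(flatten_parameters(p), function(v) paste(fmt_num(v), collapse = ","),
                    character(1)),
             collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Export arm results or reports to JSON/CSV
#'
#' Writes a `bm_arm` (or `bm_cea`) result together with provenance: engine,
#' seed, and a fingerprint of the parameter set that produced it.
#'
#' @param x a `bm_arm` or `bm_cea` object.
#' @param path output file; `.json` or `.csv` decides the format.
#' @param params the parameter set used (for the fingerprint).
#' @return `path`, invisibly.
#' @export
export_results <- function(x, path, params = bm_parameters()) {
  df <- as.data.frame(x)
  prov <- list(package = "hifucea",
               version = as.character(utils::packageVersion("hifucea")),
               parameter_hash = param_hash(params),
               seed = if (!is.null(x$seed)) x$seed else NA)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(provenance = prov, results = df), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(cbind(df, parameter_hash = prov$parameter_hash), path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_results
#' @param table a `bm_psa` object.
#' @export
export_psa_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
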