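# Shortest decimal representation that parses back to the identical double,
# so written files are both readable and exactly round-trippable.
.num_str <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

# Exact-number marker for JSON output. jsonlite rounds doubles when
# serializing, so writers tag numbers as sentinel-prefixed strings and
# .hazmix_json() unquotes them after serialization.
.json_num <- function(v) {
  if (is.null(v) || is.na(v)) return(NULL)
  paste0("\x01", .num_str(v))
}

.hazmix_json <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     na = "null", pretty = 2))
  gsub('"\\\\u0001([-+0-9.eE]+)"', "\\1", s)
}
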