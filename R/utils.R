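# Round half away from zero (narrative percentages use half-up, not the
# IEEE round-half-even of base round()).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

cot_stop <- function(msg, class = "cotmeta_error", ...) {
  abort(msg, class = class, ...)
}

`%||%` <- rlang::`%||%`

# Read a packaged (or user-supplied) YAML config, caching packaged ones.
read_config <- function(name, path = NULL) {
  if (!is.null(path)) {
    return(yaml::read_yaml(path))
  }
  if (!env_has(the, name)) {
    file <- system.file("extdata", paste0(name, ".yaml"), package = "cotmeta")
    if (file == "") cot_stop(paste0("packaged config '", name, "' not found"))
    env_poke(the, name, yaml::read_yaml(file))
  }
  env_get(the, name)
}

compact_chr <- function(x) x[!is.na(x) & nzchar(x)]
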