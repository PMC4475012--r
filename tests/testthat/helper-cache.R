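# Lazily computed shared fixtures (expensive enumerations reused across
# test files within one run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

tsrn_model <- function() cached("tsrn", load_model("TSRN"))
trn_model <- function() cached("trn", load_model("TRN"))
nosocs_model <- function() cached("nosocs", load_model("TSRN_noSOCS"))
tsrn_attractors <- function()
  cached("tsrn_at", enumerate_attractors(tsrn_model()))
tsrn_scan <- function()
  cached("tsrn_scan", perturbation_scan(tsrn_model()))
nosocs_scan <- function()
  cached("nosocs_scan", perturbation_scan(nosocs_model()))
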