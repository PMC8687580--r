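# One cached smoke-scale deprivation experiment (M = 10, N = 40) shared by
# the tests that assert on trained-network behaviour. Computed on first
# use; roughly two minutes of training plus the measurement battery.
.smoke_cache <- new.env(parent = emptyenv())

get_smoke_experiment <- function() {
  if (is.null(.smoke_cache$ex)) {
    set.seed(123)
    .smoke_cache$ex <- deprivation_experiment()
  }
  .smoke_cache$ex
}
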