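# Shared seed-42 synthetic bundle (100 transcripts), generated once per
# session and memoised; loading the bundle is also memoised because GTF
# import dominates the suite's runtime.

.txvar_test_env <- new.env(parent = emptyenv())

bundle42_dir <- function() {
  d <- file.path(tempdir(), "txvar-bundle42")
  if (!file.exists(file.path(d, "bundle.ini")))
    generate_bundle(fixture_spec(seed = 42L, n_transcripts = 100L), d)
  d
}

bundle42 <- function() {
  if (is.null(.txvar_test_env$b42))
    .txvar_test_env$b42 <- load_bundle(bundle42_dir())
  .txvar_test_env$b42
}

demo_dir <- function(layout) {
  d <- file.path(tempdir(), paste0("txvar-demo-", layout))
  if (!file.exists(file.path(d, "bundle.ini"))) demo_pdac_bundle(d, layout)
  d
}

demo_bundle <- function(layout) {
  key <- paste0("demo_", layout)
  if (is.null(.txvar_test_env[[key]]))
    .txvar_test_env[[key]] <- load_bundle(demo_dir(layout))
  .txvar_test_env[[key]]
}
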