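# Shared lazy fixtures: expensive objects are built once per test session.
.test_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .test_env)) {
    assign(key, force(expr), envir = .test_env)
  }
  get(key, envir = .test_env)
}

qed_reference <- function() {
  memo("qed_ref", read.csv(system.file("extdata", "qed_reference.csv",
                                       package = "dbppr"),
                           stringsAsFactors = FALSE))
}

# a small but min_records-compliant synthetic ADMET panel
test_panel <- function() {
  memo("panel", train_synthetic_panel(n = 500L, effect = 3, seed = 11L))
}

# fixture molecules standardized once
test_fixtures_std <- function() {
  memo("fx_std", {
    fx <- fixture_molecules()
    std <- standardize_smiles(fx$smiles,
                              label = as.numeric(fx$class == "drug"))
    stopifnot(all(std$status == "accepted"))
    cbind(fx["name"], std)
  })
}

# a trained molecule-level model over the fixture panel
test_model <- function() {
  memo("model", {
    std <- test_fixtures_std()
    train_dbpp_molecules(std[c("canonical_smiles", "label")], test_panel(),
                         algo = "gbt", gamma = 0.6, seed = 7L)
  })
}
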