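R ?= Rscript

install:
	R CMD INSTALL --no-docs --no-html --no-help .

test:
	$(R) -e 'testthat::test_dir("tests/testthat", package = "twopopgen", load_package = "installed")'

reproduce-synthetic:
	$(R) inst/cli/twopopgen.R run --seed 1 --out-dir results/synthetic

acceptance:
	$(R) scripts/acceptance.R --seed 1 --out results/acceptance.json

.PHONY: install test reproduce-synthetic acceptance
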