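# Shared fixtures: the standard bath/pipette recipes of the emulated experiments,
# built in code.

recipe_cyt_no3 <- function(mM = 200, btp = if (mM == 200) 160 else 16) {
  solution_from_salts(c(HNO3 = mM, CaCl2 = 2, MgCl2 = 2), btp_mM = btp,
                      pH = 7, label = sprintf("cyt %g NO3", mM))
}

recipe_vac_no3 <- function() {
  solution_from_salts(c(HNO3 = 200, CaCl2 = 2, MgCl2 = 2), btp_mM = 101,
                      pH = 5, label = "vac 200 NO3")
}

recipe_vac_cl <- function() {
  solution_from_salts(c(HCl = 200, CaCl2 = 2, MgCl2 = 2), btp_mM = 82,
                      pH = 5, label = "vac 200 Cl")
}

# EGTA-buffered bath: 200 HNO3 / 2 EGTA / x CaCl2 / y MgCl2, 148 BTP, pH 7
recipe_egta_bath <- function(ca_mM, mg_mM) {
  salts <- c(HNO3 = 200, EGTA = 2)
  if (ca_mM > 0) salts <- c(salts, CaCl2 = ca_mM)
  if (mg_mM > 0) salts <- c(salts, MgCl2 = mg_mM)
  solution_from_salts(salts, btp_mM = 148, pH = 7,
                      label = sprintf("EGTA bath Ca %g Mg %g", ca_mM, mg_mM))
}

# random fully dissociated salt solution for property tests
random_solution <- function() {
  salts <- c(NaNO3 = stats::runif(1, 5, 300),
             KCl = stats::runif(1, 1, 150),
             CaCl2 = stats::runif(1, 0, 5),
             MgCl2 = stats::runif(1, 0, 5))
  solution_from_salts(salts, pH = stats::runif(1, 5, 8))
}
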