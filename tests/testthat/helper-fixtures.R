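# Shared fixtures built in code at test time.

SMC13_SMILES <- paste0("CC(C)CN1C(=O)N(Cc2ccc(OC)cc2)C(=O)",
                       "C11CCN(CC1)C1Cc2ccccc2C1")

smc13 <- function() parse_smiles(SMC13_SMILES, name = "SMC13")

# A 12-residue peptide whose positions 71/72/74/81 carry V/A/L/R, the
# targets of the surrogate-model mutation set.
mutation_fixture <- function() {
  make_synthetic_peptide("GVAALSKTSVAR", chain = "A", start_resno = 70L)
}

# Small two-chain structure for deletion tests: chain A = 4 residues,
# chain B = 3 residues (stand-in for a bound chaperone peptide).
two_chain_fixture <- function() {
  a <- make_synthetic_peptide("GASV", chain = "A", start_resno = 1L)
  b <- make_synthetic_peptide("KLG", chain = "B", start_resno = 10L,
                              origin = c(0, 8, 0))
  protein_structure(rbind(a$atoms, b$atoms), source = "two-chain-fixture")
}

# Rigid, shape-asymmetric branched ligand with an embedded conformer;
# used by docking-recovery tests.
recovery_ligand <- function() {
  embed_conformers(parse_smiles("CC(N)C(O)CC(C)C", "asym"),
                   max_n = 1L, seed = 9L)
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
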