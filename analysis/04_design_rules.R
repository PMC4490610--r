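#!/usr/bin/env Rscript
# Design-rule checking: audit the working half-adder architecture and three
# deliberately broken architectures against the failure-mode catalogue, and
# demonstrate the 5'-UTR hairpin scan behind the operator-repeat rule.

suppressPackageStartupMessages(library(gatestack))
dir.create("results", showWarnings = FALSE)

devs <- default_input_devices()

cat("== Working half adder ==\n")
ha <- half_adder_design()
print(run_drc(ha, devs))

cat("\n== Two pHrpL modules on one plasmid (supercoiling switch-on) ==\n")
bad_sigma <- circuit_design(
  plasmids = list(list(id = "pHigh", copy_class = "high")),
  cassettes = list(
    list(plasmid = "pHigh",
         promoters = list(list(name = "pHrpL", sigma_class = "sigma54")),
         cds = "lambdaCI"),
    list(plasmid = "pHigh",
         promoters = list(list(name = "pHrpL", sigma_class = "sigma54")),
         cds = "GFP")))
print(run_drc(bad_sigma))

cat("\n== OR design II (dual-function AraC promoter downstream in tandem) ==\n")
or2 <- circuit_design(
  plasmids = list(list(id = "p1", copy_class = "high")),
  cassettes = list(list(
    plasmid = "p1",
    promoters = list(
      list(name = "pRHAB", regulator = "RhaS", inducer = "rhamnose"),
      list(name = "pBAD", regulator = "AraC", regulator_dual_function = TRUE,
           inducer = "arabinose")),
    cds = "RFP")),
  orthogonality_evidence = list("pBAD|pRHAB" = TRUE))
print(run_drc(or2, devs))

cat("\n== XOR design II (operator sites repeated through a tandem transcript) ==\n")
site <- function() list(identity = "CI2A", dyad_perfect = TRUE)
xor2 <- circuit_design(
  plasmids = list(list(id = "p1", copy_class = "high"),
                  list(id = "p2", copy_class = "low")),
  cassettes = list(
    list(plasmid = "p2",
         promoters = list(list(name = "pBAD", regulator = "AraC",
                               regulator_dual_function = TRUE,
                               inducer = "arabinose")),
         cds = "HrpS"),
    list(plasmid = "p2",
         promoters = list(list(name = "pRHAB", regulator = "RhaS",
                               inducer = "rhamnose")),
         cds = "HrpR"),
    list(plasmid = "p1",
         promoters = list(list(name = "pHrpL", sigma_class = "sigma54")),
         cds = "lambdaCI"),
    list(plasmid = "p1",
         promoters = list(
           list(name = "pBAD", regulator = "AraC",
                regulator_dual_function = TRUE, inducer = "arabinose",
                operator_sites = list(site(), site())),
           list(name = "pRHAB", regulator = "RhaS", inducer = "rhamnose",
                operator_sites = list(site(), site()))),
         cds = "RFP")),
  orthogonality_evidence = list("pBAD|pRHAB" = TRUE))
rx <- run_drc(xor2, devs)
print(rx)
write_circuit_json(xor2, "results/xor_design_II.json")

cat("\n== 5'-UTR hairpin scan: operator regions with 7 vs 3 stem-loops ==\n")
unit <- "GGCGCAAAAGCGCC"
spacers <- c("ATTACT", "TCCTAA", "ATCTAC", "TTCATA", "ACTATT", "TATCAT")
utr7 <- paste0(paste0(rep(unit, 6), spacers, collapse = ""), unit)
utr3 <- paste0(unit, spacers[1], unit, spacers[2], unit)
for (u in list(c("7-hairpin", utr7), c("3-hairpin", utr3))) {
  n <- count_hairpins(u[2], window = 200)$count
  cat(sprintf("%s operator region: %d hairpins, expression multiplier %.3f\n",
              u[1], n, utr_penalty(n)))
}
cat("\nMutating a repeated operator region from 7 to 3 hairpins restores\n",
    "regulated expression; 4 identical sites in one transcript is flagged\n",
    "as an error by the DRC above.\n")
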