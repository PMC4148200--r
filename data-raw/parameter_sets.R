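# Writes the packaged parameter-set fixtures (one YAML document per published
# simulation condition) into inst/extdata/parameter_sets/. Values are
# transcribed verbatim from the published parameter tables for D. melanogaster
# wild type / mutants and for the six other Drosophila species.
#
# Run from the package root: Rscript data-raw/parameter_sets.R

fields <- c("El", "Er", "Eh", "Tn", "R", "S", "xi", "Gamma", "k_i", "k_e",
            "P_Cact", "k_Deg", "k_b", "Dl0", "DlCact0", "Cact0", "r", "n", "t")

base <- function(...) {
  v <- list(...)
  stopifnot(identical(names(v), fields))
  v
}

# D. melanogaster adjusted wild-type set: the baseline every other condition
# modifies.
mel_adjusted <- base(
  El = 241.5, Er = 102.4, Eh = 25, Tn = 6000,
  R = 15000, S = 4000, xi = 2.5, Gamma = 2, k_i = 4, k_e = 1,
  P_Cact = 50, k_Deg = 1, k_b = 0.02,
  Dl0 = 36, DlCact0 = 30, Cact0 = 36,
  r = 3.08, n = 92, t = 65
)

mod <- function(b, ...) utils::modifyList(b, list(...))

sets <- list(
  # Original representative set from the source nondimensional model. P_Cact,
  # k_b, Dl0 and DlCact0 were unknown for this column (lost in the
  # nondimensionalization); the adjusted-set values are substituted so the
  # fixture is a complete runnable parameter vector.
  mel_original = mod(mel_adjusted,
    El = 245, Er = 90, Eh = 31, R = 15340, S = 4052, xi = 2.38,
    Gamma = 0.03, k_i = 1.97, k_e = 0.44, k_Deg = 1.36, n = 100),
  mel_adjusted = mel_adjusted,

  # Embryos from dl-/dl+ mothers: half maternal Dl dose; reproduced with
  # increased k_i and k_Deg (set 1), plus increased Gamma and k_e (set 2).
  dl_het_1 = mod(mel_adjusted, Gamma = 0.03, k_e = 0.44, k_Deg = 4,
                 Dl0 = 18, DlCact0 = 15),
  dl_het_2 = mod(mel_adjusted, k_Deg = 4, Dl0 = 18, DlCact0 = 15),

  # Haploid (ssm) embryos: one extra division, smaller denser nuclei.
  ssm_1 = mod(mel_adjusted, Eh = 30, Tn = 12000, Gamma = 0.03, k_e = 0.44,
              r = 2.3, n = 142, t = 55),
  ssm_2 = mod(mel_adjusted, Eh = 30, Tn = 12000, r = 2.3, n = 142, t = 55),

  # Triploid (gyn) embryos: one fewer division, larger sparser nuclei.
  gyn_1 = mod(mel_adjusted, Eh = 29.9, Tn = 3000, k_e = 0.44,
              r = 5.45, n = 72, t = 86),
  gyn_2 = mod(mel_adjusted, Eh = 29.9, Tn = 3000, r = 5.45, n = 72, t = 86),
  gyn_3 = mod(mel_adjusted, Eh = 29.9, Tn = 3000, Er = 117, r = 5.45,
              n = 72, t = 86),

  # D. busckii: small divergent species.
  bus_1 = mod(mel_adjusted, El = 189, Er = 93.4, Eh = 23.4, r = 2, n = 86),
  bus_2 = mod(mel_adjusted, El = 189, Er = 93.4, Eh = 23.4, R = 12142,
              r = 2, n = 86),
  bus_3 = mod(mel_adjusted, El = 189, Er = 93.4, Eh = 23.4, R = 12142,
              k_Deg = 0.33, r = 2, n = 86),

  # D. simulans.
  sim_1 = mod(mel_adjusted, El = 236, Er = 102.5, Eh = 30.1, r = 2.75, n = 98),
  sim_2 = mod(mel_adjusted, El = 236, Er = 102.5, Eh = 30.1, R = 19285,
              r = 2.75, n = 98),
  sim_3 = mod(mel_adjusted, El = 236, Er = 102.5, Eh = 30.1, R = 19285,
              k_Deg = 5, r = 2.75, n = 98),
  sim_4 = mod(mel_adjusted, El = 236, Er = 102.5, Eh = 30.1, R = 19285,
              k_b = 0.005, r = 2.75, n = 98),
  sim_5 = mod(mel_adjusted, El = 236, Er = 102.5, Eh = 30.1, R = 19285,
              k_e = 0.5, k_Deg = 2, k_b = 0.015, r = 2.75, n = 98),

  # D. sechellia: large sibling of D. simulans.
  sec_1 = mod(mel_adjusted, El = 286.5, Er = 134.85, Eh = 29.6, Tn = 7000,
              r = 3.5, n = 102),
  sec_2 = mod(mel_adjusted, El = 286.5, Er = 134.85, Eh = 29.6, Tn = 7000,
              R = 18571, r = 3.5, n = 102),
  sec_3 = mod(mel_adjusted, El = 286.5, Er = 134.85, Eh = 29.6, Tn = 7000,
              R = 18571, k_Deg = 1.5, r = 3.5, n = 102),
  sec_4 = mod(mel_adjusted, El = 286.5, Er = 134.85, Eh = 29.6, Tn = 7000,
              R = 18571, k_Deg = 1.5, k_b = 0.015, r = 3.5, n = 102),
  sec_5 = mod(mel_adjusted, El = 286.5, Er = 134.85, Eh = 29.6, Tn = 7000,
              R = 18571, k_e = 0.5, k_b = 0.015, r = 3.5, n = 102),

  # D. yakuba.
  yak_1 = mod(mel_adjusted, El = 251.6, Er = 114, Eh = 24.85, r = 3.4, n = 100),
  yak_2 = mod(mel_adjusted, El = 251.6, Er = 114, Eh = 24.85, R = 16578,
              r = 3.4, n = 100),
  yak_3 = mod(mel_adjusted, El = 251.6, Er = 114, Eh = 24.85, R = 16578,
              k_b = 0.01, r = 3.4, n = 100),
  yak_4 = mod(mel_adjusted, El = 251.6, Er = 114, Eh = 24.85, R = 16578,
              k_Deg = 2, r = 3.4, n = 100),

  # D. santomea: large sibling of D. yakuba.
  san_1 = mod(mel_adjusted, El = 302.45, Er = 126, Eh = 32.43, r = 3.7, n = 96),
  san_2 = mod(mel_adjusted, El = 302.45, Er = 126, Eh = 32.43, R = 15789,
              r = 3.7, n = 96),
  san_3 = mod(mel_adjusted, El = 302.45, Er = 126, Eh = 32.43, R = 15789,
              k_b = 0.01, r = 3.7, n = 96),
  san_4 = mod(mel_adjusted, El = 302.45, Er = 126, Eh = 32.43, R = 15789,
              k_Deg = 2, r = 3.7, n = 96)
)

# Species metadata: mesodermal sna percent arc-length (proxy for peak Toll
# activation range) and the last nuclear cycle reached.
meta <- list(
  mel_original = list(species = "D. melanogaster", sna_arc_pct = 21, final_cycle = 14),
  mel_adjusted = list(species = "D. melanogaster", sna_arc_pct = 21, final_cycle = 14),
  dl_het_1 = list(species = "D. melanogaster (dl-/dl+)", sna_arc_pct = 21, final_cycle = 14),
  dl_het_2 = list(species = "D. melanogaster (dl-/dl+)", sna_arc_pct = 21, final_cycle = 14),
  ssm_1 = list(species = "D. melanogaster (ssm haploid)", sna_arc_pct = 21, final_cycle = 15),
  ssm_2 = list(species = "D. melanogaster (ssm haploid)", sna_arc_pct = 21, final_cycle = 15),
  gyn_1 = list(species = "D. melanogaster (gyn triploid)", sna_arc_pct = 21, final_cycle = 13),
  gyn_2 = list(species = "D. melanogaster (gyn triploid)", sna_arc_pct = 21, final_cycle = 13),
  gyn_3 = list(species = "D. melanogaster (gyn triploid)", sna_arc_pct = 21, final_cycle = 13),
  bus_1 = list(species = "D. busckii", sna_arc_pct = 17, final_cycle = 14),
  bus_2 = list(species = "D. busckii", sna_arc_pct = 17, final_cycle = 14),
  bus_3 = list(species = "D. busckii", sna_arc_pct = 17, final_cycle = 14),
  sim_1 = list(species = "D. simulans", sna_arc_pct = 27, final_cycle = 14),
  sim_2 = list(species = "D. simulans", sna_arc_pct = 27, final_cycle = 14),
  sim_3 = list(species = "D. simulans", sna_arc_pct = 27, final_cycle = 14),
  sim_4 = list(species = "D. simulans", sna_arc_pct = 27, final_cycle = 14),
  sim_5 = list(species = "D. simulans", sna_arc_pct = 27, final_cycle = 14),
  sec_1 = list(species = "D. sechellia", sna_arc_pct = 26, final_cycle = 14),
  sec_2 = list(species = "D. sechellia", sna_arc_pct = 26, final_cycle = 14),
  sec_3 = list(species = "D. sechellia", sna_arc_pct = 26, final_cycle = 14),
  sec_4 = list(species = "D. sechellia", sna_arc_pct = 26, final_cycle = 14),
  sec_5 = list(species = "D. sechellia", sna_arc_pct = 26, final_cycle = 14),
  yak_1 = list(species = "D. yakuba", sna_arc_pct = 22.06, final_cycle = 14),
  yak_2 = list(species = "D. yakuba", sna_arc_pct = 22.06, final_cycle = 14),
  yak_3 = list(species = "D. yakuba", sna_arc_pct = 22.06, final_cycle = 14),
  yak_4 = list(species = "D. yakuba", sna_arc_pct = 22.06, final_cycle = 14),
  san_1 = list(species = "D. santomea", sna_arc_pct = 20.44, final_cycle = 14),
  san_2 = list(species = "D. santomea", sna_arc_pct = 20.44, final_cycle = 14),
  san_3 = list(species = "D. santomea", sna_arc_pct = 20.44, final_cycle = 14),
  san_4 = list(species = "D. santomea", sna_arc_pct = 20.44, final_cycle = 14)
)

dir.create("inst/extdata/parameter_sets", recursive = TRUE, showWarnings = FALSE)
for (label in names(sets)) {
  doc <- c(list(label = label), meta[[label]], sets[[label]])
  yaml::write_yaml(doc, file.path("inst/extdata/parameter_sets",
                                  paste0(label, ".yaml")))
}
cat("wrote", length(sets), "parameter-set fixtures\n")
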