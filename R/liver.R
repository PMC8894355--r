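## Packaged rat-liver central-energy-metabolism superstructure:
## glycogen metabolism, glycolysis, pyruvate fermentation, TCA cycle,
## oxidative phosphorylation, glutaminolysis, urea cycle, glutathione,
## serine-glycine interconversion, citrate shuttle and fatty-acid
## synthesis (mode-gated), plus beta-oxidation (mode-gated, off by
## default).  Reactions are canonical textbook stoichiometries written
## in major-protonation-state species so every element and the charge
## balance exactly; liver-specific chemistry: glucokinase (not
## feedback-inhibited hexokinase), glutathione synthesis run reversibly
## (the preservation-solution mechanism of ATP regeneration), serine
## made from glycine via SHMT2 (no 3-PGDH route), pyruvate fermentation
## to lactate, and a urea cycle with ornithine recycle.

#' Load the packaged liver species thermodynamics table
#'
#' @return a [thermo_db()] with the curated formation energies,
#'   enthalpies and standard deviations used by the liver model.
#' @export
liver_thermo <- function() {
  read_thermo_tsv(system.file("extdata", "liver_thermo.tsv",
                              package = "nashmet", mustWork = TRUE))
}

.rx <- function(id, eq) reaction(id, eq, reversible = TRUE)

## Every node carries the physiological phosphate buffer pair
## (H2PO4- <-> HPO4^2- + H+, pKa ~ 7.2) plus a protein/imidazole-like
## buffer pair (pKa ~ 7.0) standing in for the large intracellular
## buffering capacity: the proton economy is buffered at the tens-of-mM
## scale, keeping pH well-posed while reactions consume or release
## protons.
.add_phosphate_buffer <- function(nd) {
  pathway_node(
    nd$node_id,
    c(unname(nd$reactions),
      list(.rx(paste0("pbuf_", nd$node_id), "h2po4 -> pi + h"),
           .rx(paste0("ibuf_", nd$node_id), "hbuf -> buf + h"))),
    species_ids = union(nd$species_ids,
                        c("h2po4", "pi", "h", "hbuf", "buf")),
    feedback_links = nd$feedback_links)
}

#' Build the packaged liver metabolic network
#'
#' @param fatty_acid_synthesis include the citrate shuttle, acetyl-CoA
#'   carboxylase and fatty-acid synthesis node (default `TRUE`).
#' @param beta_oxidation include the beta-oxidation node (default
#'   `FALSE`).
#' @param db a [thermo_db()] to validate against (default the packaged
#'   [liver_thermo()]).
#' @return a validated `network_model` carrying the default initial
#'   composition (pmol/cell per node) as attribute `"composition"`.
#'   Node order is the engine's visit order: upstream glycogen
#'   metabolism and glycolysis first, then downstream pathways.
#' @export
build_liver_model <- function(fatty_acid_synthesis = TRUE,
                              beta_oxidation = FALSE,
                              db = liver_thermo()) {
  nodes <- list(
    pathway_node("glutathione", list(
      .rx("gshs", "gly + 2 atp + glu + cys -> 2 adp + 2 pi + gsh + 2 h"),
      .rx("adk2", "adenosine + atp -> amp + adp + h"),
      .rx("ak_g", "atp + amp -> 2 adp")),
      species_ids = c("gly", "atp", "glu", "cys", "adp", "pi", "gsh", "h",
                      "adenosine", "amp", "h2o")),
    pathway_node("glycogen", list(
      .rx("glyphos", "glycogen + pi -> g1p"),
      .rx("pgm1", "g1p -> g6p")),
      species_ids = c("glycogen", "pi", "g1p", "g6p", "h2o")),
    pathway_node("glycolysis", list(
      .rx("gk",    "glucose + atp -> g6p + adp + h"),
      .rx("pgi",   "g6p -> f6p"),
      .rx("pfk",   "f6p + atp -> fbp + adp + h"),
      .rx("ald",   "fbp -> dhap + g3p"),
      .rx("tpi",   "dhap -> g3p"),
      .rx("gapdh", "g3p + pi + nad -> bpg + nadh + h"),
      .rx("pgk",   "bpg + adp -> pg3 + atp"),
      .rx("pgm",   "pg3 -> pg2"),
      .rx("eno",   "pg2 -> pep + h2o"),
      .rx("pk",    "pep + adp + h -> pyr + atp")),
      species_ids = c("glucose", "atp", "g6p", "adp", "h", "f6p", "fbp",
                      "dhap", "g3p", "pi", "nad", "bpg", "nadh", "pg3",
                      "pg2", "pep", "pyr", "h2o")),
    pathway_node("fermentation", list(
      .rx("ldh", "pyr + nadh + h -> lac + nad")),
      species_ids = c("pyr", "nadh", "h", "lac", "nad", "h2o")),
    pathway_node("glutaminolysis", list(
      .rx("glnase", "gln + h2o -> glu + nh4"),
      .rx("gdh",    "glu + h2o + nad -> akg + nh4 + nadh + h")),
      species_ids = c("gln", "h2o", "glu", "nh4", "nad", "akg", "nadh",
                      "h")),
    pathway_node("tca", list(
      .rx("pdh",   "pyr + coa + nad -> accoa + co2 + nadh"),
      .rx("cs",    "accoa + oaa + h2o -> cit + coa + h"),
      .rx("acn",   "cit -> icit"),
      .rx("idh",   "icit + nad -> akg + co2 + nadh"),
      .rx("akgdh", "akg + coa + nad -> succoa + co2 + nadh"),
      .rx("sucs",  "succoa + adp + pi -> succ + coa + atp"),
      .rx("sdh",   "succ + fad -> fum + fadh2"),
      .rx("fh",    "fum + h2o -> mal"),
      .rx("mdh",   "mal + nad -> oaa + nadh + h"),
      .rx("fadox", "fadh2 + 1/2 o2 -> fad + h2o"),
      .rx("cahy_t", "co2 + h2o -> hco3 + h")),
      species_ids = c("pyr", "coa", "nad", "accoa", "co2", "nadh", "oaa",
                      "h2o", "cit", "h", "icit", "akg", "succoa", "adp",
                      "pi", "succ", "atp", "fad", "fum", "fadh2", "mal",
                      "o2", "hco3"),
      feedback_links = "oaa"),
    pathway_node("oxphos", list(
      .rx("oxphos",
          "nadh + 1/2 o2 + 5/2 adp + 5/2 pi + 7/2 h -> nad + 5/2 atp + 7/2 h2o")),
      species_ids = c("nadh", "o2", "adp", "pi", "h", "nad", "atp",
                      "h2o")),
    pathway_node("urea_cycle", list(
      .rx("cps",   "nh4 + hco3 + 2 atp -> cp + 2 adp + pi + 2 h"),
      .rx("otc",   "cp + orn -> citr + pi + h"),
      .rx("ass",   "citr + asp + atp -> argsucc + amp + ppi + h"),
      .rx("asl",   "argsucc -> arg + fum"),
      .rx("arg1",  "arg + h2o -> orn + urea"),
      .rx("ast",   "oaa + glu -> asp + akg"),
      .rx("ppase", "ppi + h2o -> 2 pi + h"),
      .rx("ak",    "atp + amp -> 2 adp"),
      .rx("nh4eq", "nh4 -> nh3 + h"),
      .rx("cahy_u", "co2 + h2o -> hco3 + h"),
      .rx("fh_u",  "fum + h2o -> mal"),
      .rx("mdh_u", "mal + nad -> oaa + nadh + h")),
      species_ids = c("nh4", "hco3", "atp", "cp", "adp", "pi", "h", "orn",
                      "citr", "asp", "argsucc", "amp", "ppi", "arg",
                      "fum", "h2o", "urea", "oaa", "glu", "akg", "nh3",
                      "co2", "mal", "nad", "nadh"),
      feedback_links = "orn"),
    pathway_node("serine_glycine", list(
      .rx("shmt", "ser + thf -> gly + mlthf + h2o"),
      .rx("gcs",  "gly + thf + nad -> mlthf + co2 + nh4 + nadh"),
      .rx("cahy_s", "co2 + h2o -> hco3 + h")),
      species_ids = c("ser", "thf", "gly", "mlthf", "h2o", "nad", "co2",
                      "nh4", "nadh", "h", "hco3"))
  )
  transports <- list(
    transport_link("t_g6p",      "glycogen",       "glycolysis",     "g6p"),
    transport_link("t_pyr_ferm", "glycolysis",     "fermentation",   "pyr"),
    transport_link("t_pyr_tca",  "glycolysis",     "tca",            "pyr"),
    transport_link("t_nadh_gly", "glycolysis",     "oxphos",         "nadh"),
    transport_link("t_nadh_ferm","glycolysis",     "fermentation",   "nadh"),
    transport_link("t_nadh_tca", "tca",            "oxphos",         "nadh"),
    transport_link("t_nad_ferm", "fermentation",   "glycolysis",     "nad"),
    transport_link("t_nadh_oxf", "oxphos",         "fermentation",   "nadh"),
    transport_link("t_h2po4_f",  "glycolysis",     "fermentation",   "h2po4"),
    transport_link("t_pi_f_gly", "fermentation",   "glycolysis",     "pi"),
    transport_link("t_nad_f_u",  "fermentation",   "urea_cycle",     "nad"),
    transport_link("t_nadh_u_f", "urea_cycle",     "fermentation",   "nadh"),
    transport_link("t_adp_ox_g", "oxphos",         "glycolysis",     "adp"),
    transport_link("t_nad_ox",   "oxphos",         "tca",            "nad"),
    transport_link("t_atp_urea", "oxphos",         "urea_cycle",     "atp"),
    transport_link("t_adp_urea", "urea_cycle",     "oxphos",         "adp"),
    transport_link("t_akg",      "glutaminolysis", "tca",            "akg"),
    transport_link("t_nh4",      "glutaminolysis", "urea_cycle",     "nh4"),
    transport_link("t_fum",      "urea_cycle",     "tca",            "fum"),
    transport_link("t_gly",      "glutathione",    "serine_glycine", "gly"),
    transport_link("t_atp_gsh",  "glutathione",    "urea_cycle",     "atp"),
    transport_link("t_atp_gly_u","glycolysis",     "urea_cycle",     "atp"),
    transport_link("t_adp_u_gly","urea_cycle",     "glycolysis",     "adp")
  )
  if (fatty_acid_synthesis) {
    nodes <- c(nodes, list(
      pathway_node("citrate_shuttle", list(
        .rx("acl",  "cit + atp + coa -> oaa + accoa + adp + pi"),
        .rx("mdhc", "oaa + nadh + h -> mal + nad")),
        species_ids = c("cit", "atp", "coa", "oaa", "accoa", "adp", "pi",
                        "nadh", "h", "mal", "nad", "h2o")),
      pathway_node("fatty_acid_synthesis", list(
        .rx("acc", "accoa + hco3 + atp -> malcoa + adp + pi + h"),
        .rx("fas",
            "accoa + malcoa + 2 nadph + 3 h -> butcoa + coa + co2 + 2 nadp + h2o"),
        .rx("cahy_f", "co2 + h2o -> hco3 + h")),
        species_ids = c("accoa", "hco3", "atp", "malcoa", "adp", "pi", "h",
                        "nadph", "butcoa", "coa", "co2", "nadp", "h2o"))))
    transports <- c(transports, list(
      transport_link("t_cit",     "tca",             "citrate_shuttle",
                     "cit"),
      transport_link("t_accoa",   "citrate_shuttle", "fatty_acid_synthesis",
                     "accoa"),
      transport_link("t_mal",     "citrate_shuttle", "tca", "mal"),
      transport_link("t_atp_fas", "oxphos",          "fatty_acid_synthesis",
                     "atp"),
      transport_link("t_atp_gly_f", "glycolysis",   "fatty_acid_synthesis",
                     "atp"),
      transport_link("t_adp_f_gly", "fatty_acid_synthesis", "glycolysis",
                     "adp")))
  }
  if (beta_oxidation) {
    nodes <- c(nodes, list(
      pathway_node("beta_oxidation", list(
        .rx("box",
            "butcoa + coa + fad + nad + h2o -> 2 accoa + fadh2 + nadh + h"),
        .rx("fadox_b", "fadh2 + 1/2 o2 -> fad + h2o")),
        species_ids = c("butcoa", "coa", "fad", "nad", "h2o", "accoa",
                        "fadh2", "nadh", "h", "o2"))))
    transports <- c(transports, list(
      transport_link("t_accoa_box", "beta_oxidation", "tca", "accoa")))
    if (fatty_acid_synthesis) {
      transports <- c(transports, list(
        transport_link("t_butcoa", "fatty_acid_synthesis", "beta_oxidation",
                       "butcoa")))
    }
  }
  nodes <- lapply(nodes, .add_phosphate_buffer)
  model <- network_model(
    nodes, transports,
    modes = list(fatty_acid_synthesis = fatty_acid_synthesis,
                 beta_oxidation = beta_oxidation),
    db = db, entry_node = "glutathione")
  attr(model, "composition") <- liver_composition(model)
  model
}

#' Default initial composition of the packaged liver model
#'
#' Physiological hepatocyte pools in mM (liver glycogen stores high,
#' glutamine and glutathione several mM, oxygen nearly absent to
#' represent the hypoxic preserved organ), converted to pmol/cell
#' through the volume basis.  Protons are seeded at pH 7.8.
#'
#' @param model a liver `network_model` (for the node list).
#' @param volume_basis litres per cell.
#' @return named list node id -> named amounts (pmol/cell), suitable
#'   for [initialize_equilibrium()].
#' @export
liver_composition <- function(model, volume_basis = .VOLUME_BASIS) {
  mm <- list(  # concentrations in mM per node
    glutathione = c(gsh = 7, gly = 2, glu = 3, cys = 0.2, atp = 1.2,
                    adp = 0.6, pi = 3, amp = 0.2, adenosine = 0.01,
                    h2o = 5000),
    glycogen = c(glycogen = 200, pi = 5, g1p = 0.1, g6p = 0.5, h2o = 5000),
    glycolysis = c(glucose = 5, atp = 2.5, adp = 0.8, pi = 5, nad = 1.5,
                   nadh = 0.05, g6p = 0.2, f6p = 0.08, fbp = 0.05,
                   dhap = 0.05, g3p = 0.05, bpg = 0.01, pg3 = 0.05,
                   pg2 = 0.02, pep = 0.02, pyr = 0.1, h2o = 5000),
    fermentation = c(pyr = 0.15, lac = 2.8, nadh = 0.2, nad = 0.5,
                     h2o = 5000),
    glutaminolysis = c(gln = 6, glu = 3, nh4 = 0.3, akg = 0.1, nad = 0.3,
                       nadh = 0.05, h2o = 5000),
    tca = c(accoa = 0.05, coa = 0.3, oaa = 0.01, cit = 0.4, icit = 0.03,
            akg = 0.2, succoa = 0.05, succ = 0.5, fum = 0.1, mal = 0.4,
            nad = 0.8, nadh = 0.2, fad = 0.1, fadh2 = 0.02, adp = 0.5,
            atp = 1, pi = 3, pyr = 0.05, co2 = 1.2, hco3 = 2, o2 = 0.05,
            h2o = 5000),
    oxphos = c(nadh = 0.3, nad = 1, o2 = 0.3, adp = 1.5, atp = 2,
               pi = 5, h2o = 5000),
    urea_cycle = c(nh4 = 0.3, nh3 = 0.05, hco3 = 10, atp = 1.5, adp = 0.5,
                   amp = 0.3, pi = 3, ppi = 0.05, orn = 0.4, citr = 0.05,
                   argsucc = 0.02, arg = 0.1, urea = 0.1, asp = 0.8,
                   glu = 1.5, oaa = 0.05, akg = 0.3, fum = 0.05, cp = 0.01,
                   co2 = 1.2, mal = 0.1, nad = 0.3, nadh = 0.05,
                   h2o = 5000),
    serine_glycine = c(ser = 0.5, gly = 1.5, thf = 0.02, mlthf = 0.01,
                       nad = 0.2, nadh = 0.03, co2 = 0.5, hco3 = 1,
                       nh4 = 0.1, h2o = 5000),
    citrate_shuttle = c(cit = 0.3, atp = 0.8, adp = 0.3, coa = 0.2,
                        accoa = 0.05, oaa = 0.02, mal = 0.3, nad = 0.3,
                        nadh = 0.1, pi = 2, h2o = 5000),
    fatty_acid_synthesis = c(accoa = 0.1, malcoa = 0.02, coa = 0.3,
                             butcoa = 0.05, nadph = 0.2, nadp = 0.1,
                             hco3 = 5, atp = 1, adp = 0.4, pi = 2,
                             h2o = 5000),
    beta_oxidation = c(butcoa = 0.1, coa = 0.3, accoa = 0.05, nad = 0.5,
                       nadh = 0.1, fad = 0.05, fadh2 = 0.01, h2o = 5000)
  )
  ph0 <- 7.8  # seed protons at physiological pH
  h_mm <- 10^(-ph0) * 1e3 / length(model$nodes)
  out <- list()
  for (nid in names(model$nodes)) {
    conc <- mm[[nid]]
    if (is.null(conc)) stop("no packaged composition for node '", nid, "'")
    conc <- conc[names(conc) %in% model$nodes[[nid]]$species_ids]
    if (!"pi" %in% names(conc)) conc[["pi"]] <- 2
    conc[["h2po4"]] <- conc[["pi"]] / 4  # pKa 7.2 buffer poised near pH 7.8
    conc[["hbuf"]] <- 8                  # imidazole-like buffer, pKa ~7.0
    conc[["buf"]] <- 25
    if ("h" %in% model$nodes[[nid]]$species_ids) conc[["h"]] <- h_mm
    out[[nid]] <- mM_to_amount(conc, volume_basis)
  }
  out
}
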