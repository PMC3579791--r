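# Study-shaped fixtures: the 16-taxon macropodid taxon set, the two dated
# guide trees, locus configurations matching the real alignment dimensions,
# and an end-to-end dataset generator with retained truth.

#' The macropodid taxon set used throughout
#'
#' Sixteen taxa: two potoroid outgroups, Lagostrophus, the two Dendrolagini,
#' two Lagorchestes, the swamp wallaby (Wallabia bicolor) and eight Macropus
#' species across the three subgenera, including the black-gloved wallaby
#' M. irma (the introgression focal taxon).
#'
#' @return named list of character vectors grouping the taxa.
#' @export
macropodid_taxa <- function() {
  list(
    potoroids = c("A_rufescens", "P_tridactylus"),
    lagostrophus = "Lagostrophus_fasciatus",
    dendrolagini = c("Petrogale_xanthopus", "Dendrolagus_dorianus"),
    lagorchestes = c("L_hirsutus", "L_conspicillatus"),
    wallabia = "W_bicolor",
    m_macropus = c("M_giganteus", "M_fuliginosus"),
    m_osphranter = c("M_rufus", "M_robustus"),
    focal = "M_irma",
    core_notamacropus = c("M_rufogriseus", "M_eugenii", "M_agilis")
  )
}

.tx <- function() macropodid_taxa()

#' Macropus (all subgenera, including the focal wallaby)
#' @return character vector of 8 taxa.
#' @export
macropus_clade <- function() {
  g <- .tx()
  c(g$m_macropus, g$m_osphranter, g$focal, g$core_notamacropus)
}

#' Notamacropus (the focal wallaby plus core Notamacropus)
#' @return character vector of 4 taxa.
#' @export
notamacropus_clade <- function() {
  g <- .tx()
  c(g$focal, g$core_notamacropus)
}

# topology shared by both guide trees below the Macropus/Wallabia neighborhood
.base_newick <- function(macropodini) {
  g <- .tx()
  sprintf(
    "((%s,%s),(%s,((%s,%s),((%s,%s),%s))));",
    g$potoroids[1], g$potoroids[2], g$lagostrophus,
    g$dendrolagini[1], g$dendrolagini[2],
    g$lagorchestes[1], g$lagorchestes[2], macropodini)
}

#' The two dated guide trees of the simulation study
#'
#' `combined`: topology and node ages of the combined-data species tree
#' (Wallabia sister to Macropus; within Macropus, Notamacropus sister to
#' M.(Macropus)+M.(Osphranter); root 20.0, Potoroidae 17.0, Macropodidae
#' 14.4, Dendrolagini/Macropodini 7.6, Lagorchestes split 6.6,
#' Macropus/Wallabia 5.3, Macropus 4.8, M.(Macropus)/M.(Osphranter) 4.4,
#' core-Notamacropus crown 3.4 Ma). `nuclear_only`: the nuclear species tree
#' (Wallabia sister to Notamacropus; 20.0, 16.4, 17.7, 10.7, 8.8, 7.3, 6.8,
#' 6.7, 5.8 Ma). Node ages not reported (within-subgenus splits, the
#' Dendrolagini and Lagorchestes crowns) are interpolated evenly between the
#' nearest dated crown and the tips. The focal wallaby M. irma is grafted
#' mid-stem onto the core-Notamacropus lineage of each tree (4.1 Ma combined,
#' 6.25 Ma nuclear-only), mirroring its treatment in the study design. Both
#' trees are scaled to a root height of 20 Ma.
#'
#' @return list with ultrametric `phylo` elements `combined` and
#'   `nuclear_only` (16 taxa each).
#' @export
study_guide_trees <- function() {
  g <- .tx()
  core <- sprintf("(%s,(%s,%s))", g$core_notamacropus[1],
                  g$core_notamacropus[2], g$core_notamacropus[3])
  mm <- sprintf("(%s,%s)", g$m_macropus[1], g$m_macropus[2])
  mo <- sprintf("(%s,%s)", g$m_osphranter[1], g$m_osphranter[2])
  all16 <- unlist(g, use.names = FALSE)
  macropodidae <- setdiff(all16, c(g$potoroids, "M_irma"))

  # combined-data tree: Wallabia sister to Macropus; (core-Nota,(MM,MO))
  macropus_c <- sprintf("(%s,(%s,%s))", core, mm, mo)
  macropodini_c <- sprintf("(%s,%s)", g$wallabia, macropus_c)
  topo_c <- parse_newick(.base_newick(macropodini_c))
  macropus_wo_irma <- setdiff(macropus_clade(), "M_irma")
  ages_c <- list(
    list(clade = setdiff(all16, "M_irma"), age = 20.0),
    list(clade = g$potoroids, age = 17.0),
    list(clade = macropodidae, age = 14.4),
    list(clade = setdiff(macropodidae, g$lagostrophus), age = 7.6),
    list(clade = c(g$lagorchestes, g$wallabia, macropus_wo_irma), age = 6.6),
    list(clade = c(g$wallabia, macropus_wo_irma), age = 5.3),
    list(clade = macropus_wo_irma, age = 4.8),
    list(clade = c(g$m_macropus, g$m_osphranter), age = 4.4),
    list(clade = g$core_notamacropus, age = 3.4))
  combined <- chronogram_from_ages(topo_c, ages_c, interpolate = TRUE)
  combined <- graft_taxon(combined, "M_irma", g$core_notamacropus,
                          attach_age = (3.4 + 4.8) / 2)
  combined <- scale_root_height(combined, 20)

  # nuclear-only tree: (MM,(MO,(Wallabia,Nota)))
  macropodini_n <- sprintf("(%s,(%s,(%s,%s)))", mm, mo, g$wallabia, core)
  topo_n <- parse_newick(.base_newick(macropodini_n))
  ages_n <- list(
    list(clade = setdiff(all16, "M_irma"), age = 20.0),
    list(clade = g$potoroids, age = 16.4),
    list(clade = macropodidae, age = 17.7),
    list(clade = setdiff(macropodidae, g$lagostrophus), age = 10.7),
    list(clade = c(g$lagorchestes, g$wallabia, macropus_wo_irma), age = 8.8),
    list(clade = c(g$wallabia, macropus_wo_irma), age = 7.3),
    list(clade = c(g$wallabia, g$m_osphranter, g$core_notamacropus),
         age = 6.8),
    list(clade = c(g$wallabia, g$core_notamacropus), age = 6.7),
    list(clade = g$core_notamacropus, age = 5.8))
  nuclear <- chronogram_from_ages(topo_n, ages_n, interpolate = TRUE)
  nuclear <- graft_taxon(nuclear, "M_irma", g$core_notamacropus,
                         attach_age = (5.8 + 6.7) / 2)
  nuclear <- scale_root_height(nuclear, 20)
  list(combined = combined, nuclear_only = nuclear)
}

#' Default substitution models for the simulated loci
#'
#' Mitochondrial: GTR+G with a strong transition bias and low alpha, the
#' flavor typical of mammalian mtDNA protein/rRNA concatenations. Nuclear:
#' HKY+G with mild rate heterogeneity, typical of the exonic loci emulated.
#'
#' @return list with `mt` and `nuclear` [subst_model()]s.
#' @export
default_models <- function() {
  list(
    mt = subst_model("GTR", base_freqs = c(0.34, 0.26, 0.12, 0.28),
                     rates = c(1.3, 17, 1.3, 0.6, 20, 1),
                     gamma_shape = 0.4),
    nuclear = subst_model("HKY", base_freqs = c(0.29, 0.21, 0.23, 0.27),
                          kappa = 3, gamma_shape = 0.8)
  )
}

#' Default locus set matching the study's alignment dimensions
#'
#' One mitochondrial locus of 5,593 bp and five nuclear loci totalling
#' 5,988 bp (1,198/1,198/1,198/1,197/1,197; only the total is constrained by
#' the study design). Mutation rates are documented placeholders: mt 1.0e-2
#' and nuclear 1.5e-3 substitutions/site/Myr, converted to per-generation
#' units with the supplied generation time.
#'
#' @param generation_time years/generation (default 7).
#' @return list with elements `mt` (a [locus_model()]) and `nuclear` (list of
#'   five).
#' @export
default_loci <- function(generation_time = 7) {
  mods <- default_models()
  per_gen <- function(rate_per_myr) rate_per_myr * generation_time / 1e6
  nuc_names <- c("IRBP", "vWF", "ApoB", "BRCA1", "RAG1")
  nuc_len <- c(1198, 1198, 1198, 1197, 1197)
  list(
    mt = locus_model("mtDNA", 5593, "mitochondrial",
                     mu = per_gen(1.0e-2), model = mods$mt),
    nuclear = Map(function(nm, ln) {
      locus_model(nm, ln, "nuclear_autosomal", mu = per_gen(1.5e-3),
                  model = mods$nuclear)
    }, nuc_names, nuc_len)
  )
}

#' Focal clades for the support scans
#'
#' `nuclear_scan`: the five short-stem clades whose gene support is tallied
#' on the combined guide tree. `mt_scan`: the groupings tallied on the
#' nuclear-only guide tree (Wallabia+Notamacropus, Notamacropus, plus
#' Macropus monophyly).
#'
#' @param type `"nuclear_scan"` or `"mt_scan"`.
#' @return named list of character vectors.
#' @export
focal_clades <- function(type = c("nuclear_scan", "mt_scan")) {
  type <- match.arg(type)
  g <- .tx()
  if (type == "nuclear_scan") {
    list(
      Lagorchestes_Wallabia_Macropus = c(g$lagorchestes, g$wallabia,
                                         macropus_clade()),
      Wallabia_Macropus = c(g$wallabia, macropus_clade()),
      Macropus = macropus_clade(),
      MMacropus_MOsphranter = c(g$m_macropus, g$m_osphranter),
      Notamacropus = notamacropus_clade())
  } else {
    list(
      Wallabia_Notamacropus = c(g$wallabia, notamacropus_clade()),
      Notamacropus = notamacropus_clade(),
      Macropus = macropus_clade())
  }
}

#' Study configuration bundle
#'
#' @param guide `"combined"` or `"nuclear_only"`.
#' @param ne_grid nuclear-reference Ne grid.
#' @param generation_time years/generation.
#' @return list of class `study_config`.
#' @export
study_config <- function(guide = c("combined", "nuclear_only"),
                         ne_grid = c(1e3, 1e4, 1e5, 1e6),
                         generation_time = 7) {
  guide <- match.arg(guide)
  trees <- study_guide_trees()
  loci <- default_loci(generation_time)
  structure(list(
    guide_name = guide,
    guide = trees[[if (guide == "combined") "combined" else "nuclear_only"]],
    loci = loci, ne_grid = ne_grid, generation_time = generation_time,
    taxa = unlist(macropodid_taxa(), use.names = FALSE)),
    class = "study_config")
}

#' Generate one fully synthetic multi-locus dataset with known truth
#'
#' Simulates a genealogy and alignment for the mitochondrial locus and each
#' nuclear locus on the configured guide tree, retaining the true genealogies.
#' When `dir` is given, writes one FASTA per locus, the species tree and true
#' genealogies as Newick, and a JSON manifest (seed, Ne, locus table) that
#' suffices to regenerate the dataset bit-identically.
#'
#' @param config a [study_config()].
#' @param Ne nuclear-reference effective population size.
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return list: `alignments` (named), `genealogies` (named), `species_tree`,
#'   `manifest`.
#' @export
generate_dataset <- function(config, Ne, seed, dir = NULL) {
  loci <- c(list(config$loci$mt), unname(config$loci$nuclear))
  seeds <- .substream_seeds(seed, length(loci))
  params <- pop_params(Ne, config$generation_time)
  alns <- list(); gens <- list()
  for (i in seq_along(loci)) {
    set.seed(seeds[i])
    locus <- loci[[i]]
    gen <- simulate_genealogy(config$guide, params, locus)
    alns[[locus$name]] <- simulate_alignment(gen, locus$model, locus$length)
    gens[[locus$name]] <- gen
  }
  manifest <- list(
    seed = seed, Ne = Ne, guide = config$guide_name,
    generation_time = config$generation_time,
    loci = data.frame(
      name = vapply(loci, `[[`, character(1), "name"),
      length = vapply(loci, `[[`, integer(1), "length"),
      ploidy = vapply(loci, `[[`, character(1), "ploidy_class"),
      mu = vapply(loci, `[[`, numeric(1), "mu")))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(alns)) {
      write_fasta(alns[[nm]], file.path(dir, paste0(nm, ".fasta")))
    }
    ape::write.tree(config$guide, file.path(dir, "species_tree.nwk"))
    ape::write.tree(
      do.call(c, lapply(gens, function(g) g$tree_subs)),
      file.path(dir, "true_genealogies.nwk"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(alignments = alns, genealogies = gens, species_tree = config$guide,
       manifest = manifest)
}
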