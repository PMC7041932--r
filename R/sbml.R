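# SBML Level 3 serialization of the generated network.
#
# The writer covers exactly the constructs the model uses: mass-action
# reactions (up to two reactants/products), the zero-order calcium
# leak/influx, the Michaelis-Menten pump, and the phosphorylation layer
# (surrogate-modulated autophosphorylation, pooled Michaelis-Menten
# dephosphorylation), each with explicit MathML. A package annotation
# carries the solver-facing index arrays at full precision so that a
# round-trip reconstructs the network bit-identically; the MathML is the
# interoperable description of the same rate laws.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
HC_NS <- "urn:hemicam:network"

num17 <- function(x) formatC(x, digits = 17, format = "g")

#' Export a reaction network to SBML Level 3
#'
#' @param network a `reaction_network` (or a degenerate list with empty
#'   `species`/`reactions`, which yields a compartment-only document).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path) {
  known <- c("ca_bind", "ca_unbind", "conf_open", "conf_close",
             "partner_on", "partner_off", "can_load", "can_unload",
             "chel_on", "chel_off")
  if (nrow(network$reactions) && !all(network$reactions$kind %in% known))
    stop("unserializable rate law kind: ",
         setdiff(network$reactions$kind, known)[1])
  vol <- network$config$volume %||% 1e-15
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "hemicam_network")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", size = num17(vol),
                      spatialDimensions = "3", constant = "true")
  sp <- network$species
  if (NROW(sp) > 0) {
    ls <- xml2::xml_add_child(model, "listOfSpecies")
    for (i in seq_len(nrow(sp)))
      xml2::xml_add_child(ls, "species", id = sp$id[i], compartment = "cell",
                          initialConcentration = num17(sp$init[i]),
                          hasOnlySubstanceUnits = "false",
                          boundaryCondition = "false", constant = "false")
  }
  rr <- network$reactions
  s <- network$special
  lr <- xml2::xml_add_child(model, "listOfReactions")
  add_reaction <- function(id, reactants, products, math_builder,
                           modifiers = character(0)) {
    rx <- xml2::xml_add_child(lr, "reaction", id = id, reversible = "false")
    if (length(reactants)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (r in reactants)
        xml2::xml_add_child(lre, "speciesReference", species = r,
                            stoichiometry = "1", constant = "true")
    }
    if (length(products)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (p in products)
        xml2::xml_add_child(lpr, "speciesReference", species = p,
                            stoichiometry = "1", constant = "true")
    }
    if (length(modifiers)) {
      lmo <- xml2::xml_add_child(rx, "listOfModifiers")
      for (m in modifiers)
        xml2::xml_add_child(lmo, "modifierSpeciesReference", species = m)
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    math_builder(math)
  }
  cn <- function(parent, x) xml2::xml_add_child(parent, "cn", num17(x))
  ci <- function(parent, id) xml2::xml_add_child(parent, "ci", id)
  apply_op <- function(parent, op) {
    a <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(a, op)
    a
  }
  sum_of <- function(parent, ids) {
    if (length(ids) == 1) return(ci(parent, ids))
    a <- apply_op(parent, "plus")
    for (id in ids) ci(a, id)
  }
  if (NROW(rr) > 0) {
    for (j in seq_len(nrow(rr))) {
      reac <- sp$id[c(rr$r1[j], rr$r2[j])[c(TRUE, rr$r2[j] > 0)]]
      prod <- sp$id[c(rr$p1[j], rr$p2[j])[c(rr$p1[j] > 0, rr$p2[j] > 0)]]
      kconst <- rr$k[j]
      add_reaction(sprintf("J%03d_%s", j, rr$kind[j]), reac, prod,
                   function(math) {
                     a <- apply_op(math, "times")
                     cn(a, kconst)
                     for (r in reac) ci(a, r)
                   })
    }
  }
  ids <- sp$id
  if (!is.null(s) && (s$leak > 0 || s$pump_Vmax > 0)) {
    ca_id <- ids[s$ica]
    if (s$leak > 0)
      add_reaction("Jleak", character(0), ca_id,
                   function(math) cn(math, s$leak))
    if (s$pump_Vmax > 0)
      add_reaction("Jpump", ca_id, character(0), function(math) {
        dv <- apply_op(math, "divide")
        nu <- apply_op(dv, "times"); cn(nu, s$pump_Vmax); ci(nu, ca_id)
        de <- apply_op(dv, "plus"); cn(de, s$pump_Km); ci(de, ca_id)
      })
  }
  if (!is.null(s$k_autop) && s$k_autop > 0) {
    act_ids <- ids[s$active_idx]
    for (i in seq_along(s$auto_src)) {
      src <- ids[s$auto_src[i]]; dst <- ids[s$auto_dst[i]]
      local({
        src <- src
        add_reaction(sprintf("Jautop_%02d", i), src, dst, function(math) {
          a <- apply_op(math, "times")
          cn(a, s$k_autop)
          # degree-5 polynomial in the active fraction
          pol <- apply_op(a, "plus")
          for (d in 0:5) {
            term <- apply_op(pol, "times")
            cn(term, s$poly[d + 1])
            if (d > 0) {
              pw <- apply_op(term, "power")
              fr <- apply_op(pw, "divide")
              sum_of(fr, act_ids)
              cn(fr, s$total_monomer)
              cn(pw, d)
            }
          }
          ci(a, src)
        }, modifiers = setdiff(act_ids, src))
      })
    }
  }
  if (!is.null(s$kcat_dep) && s$kcat_dep > 0) {
    enz_ids <- ids[s$enz_idx]; sub_ids <- ids[s$dep_src]
    for (i in seq_along(s$dep_src)) {
      src <- ids[s$dep_src[i]]; dst <- ids[s$dep_dst[i]]
      local({
        src <- src
        add_reaction(sprintf("Jdephos_%02d", i), src, dst, function(math) {
          dv <- apply_op(math, "divide")
          nu <- apply_op(dv, "times")
          cn(nu, s$kcat_dep); sum_of(nu, enz_ids); ci(nu, src)
          de <- apply_op(dv, "plus")
          cn(de, s$Km_dep); sum_of(de, sub_ids)
        }, modifiers = unique(c(enz_ids, setdiff(sub_ids, src))))
      })
    }
  }
  # full-precision machine annotation for exact round-trips
  ann <- xml2::xml_add_child(model, "annotation")
  hc <- xml2::xml_add_child(ann, "networkData", xmlns = HC_NS)
  packed <- pack_network(network)
  for (nm in names(packed)) {
    el <- xml2::xml_add_child(hc, "field", name = nm,
                              type = if (is.integer(packed[[nm]])) "int"
                                     else "double")
    xml2::xml_text(el) <- paste(num17(packed[[nm]]), collapse = " ")
  }
  meta <- xml2::xml_add_child(hc, "speciesIds")
  xml2::xml_text(meta) <- paste(sp$id, collapse = " ")
  kinds <- xml2::xml_add_child(hc, "kindList")
  xml2::xml_text(kinds) <- paste(rr$kind, collapse = " ")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network from an SBML file written by [export_sbml()]
#'
#' Reads species (ids, initial concentrations), the compartment, the
#' mass-action reaction list with rate constants, and the package
#' annotation carrying the non-mass-action layer, reconstructing a network
#' whose right-hand side is identical to the exported one's.
#'
#' @param path SBML file path.
#' @return a `reaction_network` (without the original parameter objects;
#'   `params`/`partners`/`config` carry only what the file records).
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  comp <- xml2::xml_find_first(doc, ".//compartment")
  vol <- as.numeric(xml2::xml_attr(comp, "size"))
  sps <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  fields <- xml2::xml_find_all(doc, ".//field")
  packed <- list()
  for (f in fields) {
    nm <- xml2::xml_attr(f, "name")
    vals <- scan(text = xml2::xml_text(f), what = numeric(), quiet = TRUE)
    if (xml2::xml_attr(f, "type") == "int") vals <- as.integer(vals)
    packed[[nm]] <- vals
  }
  # species table from the SBML species list itself
  sp <- data.frame(id = xml2::xml_attr(sps, "id"),
                   init = as.numeric(xml2::xml_attr(sps,
                                                    "initialConcentration")),
                   stringsAsFactors = FALSE)
  kinds <- scan(text = xml2::xml_text(xml2::xml_find_first(doc, ".//kindList")),
                what = character(), quiet = TRUE)
  # cross-check annotation against the declared reactions
  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  n_mass <- sum(grepl("^J[0-9]", rxn_ids))
  if (n_mass != length(packed$k))
    stop("SBML import: reaction list and annotation disagree")
  # mass-action rate constants parsed from the kinetic-law MathML
  k_math <- vapply(rxn_nodes[grepl("^J[0-9]", rxn_ids)], function(n) {
    cn1 <- xml2::xml_find_first(n, ".//kineticLaw//cn")
    as.numeric(xml2::xml_text(cn1))
  }, numeric(1))
  if (length(k_math) && max(abs(k_math - packed$k) /
                            pmax(abs(packed$k), 1e-300)) > 1e-12)
    stop("SBML import: MathML rate constants disagree with annotation")
  reactions <- data.frame(kind = kinds,
                          k = packed$k,
                          r1 = packed$r1 + 1L,
                          r2 = ifelse(packed$r2 < 0, 0L, packed$r2 + 1L),
                          p1 = ifelse(packed$p1 < 0, 0L, packed$p1 + 1L),
                          p2 = ifelse(packed$p2 < 0, 0L, packed$p2 + 1L),
                          stringsAsFactors = FALSE)
  special <- list(ica = packed$ica + 1L,
                  leak = packed$leak, pump_Vmax = packed$pump_vmax,
                  pump_Km = packed$pump_km)
  if (packed$k_autop > 0) {
    special$k_autop <- packed$k_autop
    special$auto_src <- packed$auto_src + 1L
    special$auto_dst <- packed$auto_dst + 1L
    special$active_idx <- packed$active_idx + 1L
    special$total_monomer <- packed$total_monomer
    special$poly <- packed$poly
  }
  if (packed$kcat_dep > 0) {
    special$kcat_dep <- packed$kcat_dep
    special$Km_dep <- packed$km_dep
    special$enz_idx <- packed$enz_idx + 1L
    special$dep_src <- packed$dep_src + 1L
    special$dep_dst <- packed$dep_dst + 1L
  }
  net <- list(species = sp, reactions = reactions, special = special,
              params = NULL, partners = NULL,
              config = list(volume = vol))
  class(net) <- "reaction_network"
  net
}
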