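# Synthetic-taxonomy simulator: generates a ground-truth ranked tree with
# planted synonyms, common names, misspellings, extinct/disused taxa,
# subspecies and deliberate homonyms, then fragments it into realistic
# backbone / specialist / fossil source files so every pipeline stage can be
# tested end-to-end without any download. The expected merge result is
# derived declaratively from the planted facts, independent of the merge
# engine's code path.

#' Simulation parameters
#'
#' All randomness flows from the single \code{seed} through one generator
#' stream, so equal parameters give byte-identical sources and ground truth.
#'
#' @param n_species number of species leaves (>= 1).
#' @param genus_size_mean mean species per genus.
#' @param ladder ordered rank names used for the supraspecific hierarchy.
#' @param synonym_rate probability a term carries a planted taxonomic
#'   synonym.
#' @param commonname_rate probability a species carries a common name.
#' @param misspelling_rate probability a name in an ontology-format source
#'   carries a planted misspelling synonym.
#' @param extinct_fraction probability a genus is entirely extinct (half
#'   that for whole families).
#' @param disused_fraction probability an extinct genus or family is marked
#'   disused in the fossil source.
#' @param trace_fraction rate of junk trace-material rows planted in the
#'   fossil table (relative to the number of extinct taxa).
#' @param invalid_fraction probability an extinct genus gets an invalid
#'   pseudo-taxon interposed above it in the fossil table.
#' @param parentless_fraction rate of junk rows lacking any parent
#'   classification.
#' @param subspecies_rate probability an extant species carries a
#'   subspecies.
#' @param homonym_rate probability an extant genus is renamed to collide
#'   with a genus in another family (exercises match disambiguation).
#' @param seed integer random seed.
#' @return a \code{sim_params} list.
#' @export
sim_params <- function(n_species = 500, genus_size_mean = 3,
                       ladder = c("class", "order", "family", "genus",
                                  "species"),
                       synonym_rate = 0.15, commonname_rate = 0.25,
                       misspelling_rate = 0.05, extinct_fraction = 0.15,
                       disused_fraction = 0.2, trace_fraction = 0.08,
                       invalid_fraction = 0.1, parentless_fraction = 0.02,
                       subspecies_rate = 0.06, homonym_rate = 0.02,
                       seed = 1) {
  p <- list(n_species = as.integer(n_species),
            genus_size_mean = genus_size_mean, ladder = ladder,
            synonym_rate = synonym_rate, commonname_rate = commonname_rate,
            misspelling_rate = misspelling_rate,
            extinct_fraction = extinct_fraction,
            disused_fraction = disused_fraction,
            trace_fraction = trace_fraction,
            invalid_fraction = invalid_fraction,
            parentless_fraction = parentless_fraction,
            subspecies_rate = subspecies_rate, homonym_rate = homonym_rate,
            seed = as.integer(seed))
  probs <- c("synonym_rate", "commonname_rate", "misspelling_rate",
             "extinct_fraction", "disused_fraction", "trace_fraction",
             "invalid_fraction", "parentless_fraction", "subspecies_rate",
             "homonym_rate")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  }
  if (p$n_species < 1) stop("n_species must be >= 1")
  structure(p, class = "sim_params")
}

# pronounceable pseudo-Latin name factory with a global collision check
make_namer <- function() {
  used <- new.env(parent = emptyenv())
  onsets <- c("b", "c", "d", "g", "l", "m", "n", "p", "r", "s", "t", "th",
              "ch", "br", "cr", "dr", "pl", "st", "tr", "ph")
  vowels <- c("a", "e", "i", "o", "u", "ae", "io")
  cap_end <- c("us", "a", "is", "ops", "ia", "odon", "ichthys", "urus",
               "ax", "oma")
  low_end <- c("us", "a", "um", "is", "ii", "ensis", "atus", "ella")
  gen <- function(capital) {
    repeat {
      k <- sample(2:3, 1)
      core <- paste0(paste0(sample(onsets, k, replace = TRUE),
                            sample(vowels, k, replace = TRUE)),
                     collapse = "")
      w <- paste0(core,
                  if (capital) sample(cap_end, 1) else sample(low_end, 1))
      if (capital) {
        w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
      }
      if (!exists(w, envir = used)) {
        assign(w, TRUE, envir = used)
        return(w)
      }
    }
  }
  claim <- function(w) {
    if (exists(w, envir = used)) return(FALSE)
    assign(w, TRUE, envir = used)
    TRUE
  }
  list(gen = gen, claim = claim)
}

# deterministic letter-swap misspelling with collision check
misspell <- function(name, namer) {
  letters_at <- which(strsplit(name, "")[[1]] %in% c(letters, LETTERS))
  pos <- letters_at[letters_at > 1]
  if (!length(pos)) return(NA_character_)
  for (try in 1:20) {
    ch <- strsplit(name, "")[[1]]
    i <- pos[sample.int(length(pos), 1)]
    ch <- append(ch, ch[i], after = i)  # doubled letter
    w <- paste0(ch, collapse = "")
    if (namer$claim(w)) return(w)
  }
  NA_character_
}

# split n into parts with mean `mean_size` (>= 1 each)
partition_sizes <- function(n, mean_size) {
  if (n <= 0) return(integer(0))
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, 1L + stats::rpois(1, max(mean_size - 1, 0.1)))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  sizes[sizes > 0]
}

#' Generate a ground-truth taxonomy with planted features
#'
#' Emulates the statistical shape of the real inputs: a backbone-wide tree
#' with two designated specialist clades (an ontology-format fish-like clade
#' and a checklist-format amphibian-like clade), background clades covered
#' only by the backbone, extinct genera and families (some disused), planted
#' typed synonyms, common names, misspellings, subspecies, and deliberate
#' genus homonyms.
#'
#' @param params a [sim_params()] list.
#' @return a list of class \code{sim_taxonomy}: \code{graph} — the
#'   ground-truth [taxonomy_graph()]; \code{truth} — a list with the
#'   \code{terms} table, planted \code{synonyms}, \code{junk} fossil rows,
#'   \code{mixed} families, and the declaratively derived \code{expected}
#'   merge result; \code{params}.
#' @export
generate_taxonomy <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  vocab <- default_rank_vocabulary()
  namer <- make_namer()

  terms <- data.frame(name = character(0), rank = character(0),
                      parent = integer(0), role = character(0),
                      extinct = logical(0), disused = logical(0),
                      subsp = logical(0), stringsAsFactors = FALSE)
  add <- function(name, rank, parent, role) {
    terms[nrow(terms) + 1L, ] <<- list(name, rank, parent, role, FALSE,
                                       FALSE, FALSE)
    nrow(terms)
  }

  root <- add("Vertebrata", "", 0L, "backbone")
  namer$claim("Vertebrata")
  clades <- data.frame(
    idx = c(add("Actinopterygii", "class", root, "obo"),
            add("Amphibia", "class", root, "tabular"),
            add(namer$gen(TRUE), "class", root, "backbone"),
            add(namer$gen(TRUE), "class", root, "backbone")),
    role = c("obo", "tabular", "backbone", "backbone"),
    weight = c(0.35, 0.25, 0.2, 0.2), stringsAsFactors = FALSE)
  namer$claim("Actinopterygii"); namer$claim("Amphibia")

  sp_counts <- stats::rmultinom(1, params$n_species, clades$weight)[, 1]
  sp_counts <- pmax(sp_counts, 1L)

  genus_rows <- integer(0)
  genus_target <- integer(0)
  for (ci in seq_len(nrow(clades))) {
    role <- clades$role[ci]
    gsizes <- partition_sizes(sp_counts[ci], params$genus_size_mean)
    fsizes <- partition_sizes(length(gsizes), 3)
    osizes <- partition_sizes(length(fsizes), 3)
    gi <- 1L
    fi <- 1L
    for (os in osizes) {
      o <- add(namer$gen(TRUE), "order", clades$idx[ci], role)
      for (fs in rep_len(1, os)) {
        f <- add(namer$gen(TRUE), "family", o, role)
        for (gs in seq_len(fsizes[fi])) {
          g <- add(namer$gen(TRUE), "genus", f, role)
          genus_rows <- c(genus_rows, g)
          genus_target <- c(genus_target, gsizes[gi])
          gi <- gi + 1L
        }
        fi <- fi + 1L
        if (fi > length(fsizes)) break
      }
      if (fi > length(fsizes)) break
    }
  }

  # extinct subtrees: whole families (rarely) and individual genera
  fam_rows <- which(terms$rank == "family")
  for (f in fam_rows) {
    if (stats::runif(1) < params$extinct_fraction / 2) {
      terms$extinct[f] <- TRUE
    }
  }
  for (k in seq_along(genus_rows)) {
    g <- genus_rows[k]
    if (terms$extinct[terms$parent[g]] ||
        stats::runif(1) < params$extinct_fraction) {
      terms$extinct[g] <- TRUE
    }
  }
  # a higher taxon all of whose members are extinct is itself extinct (it
  # can then only be carried by the fossil source); clade roots stay extant
  for (f in fam_rows) {
    kids <- which(terms$parent == f)
    if (length(kids) && all(terms$extinct[kids])) terms$extinct[f] <- TRUE
  }
  ord_rows <- which(terms$rank == "order")
  for (o in ord_rows) {
    kids <- which(terms$parent == o)
    if (length(kids) && all(terms$extinct[kids])) terms$extinct[o] <- TRUE
  }

  # disused marking among extinct higher taxa
  for (i in c(ord_rows[terms$extinct[ord_rows]],
              fam_rows[terms$extinct[fam_rows]],
              genus_rows[terms$extinct[genus_rows]])) {
    if (stats::runif(1) < params$disused_fraction) terms$disused[i] <- TRUE
  }

  # deliberate homonyms among extant genera in different families
  extant_gen <- genus_rows[!terms$extinct[genus_rows]]
  if (length(extant_gen) >= 2 && params$homonym_rate > 0) {
    for (g in extant_gen) {
      if (stats::runif(1) >= params$homonym_rate) next
      donors <- extant_gen[terms$parent[extant_gen] != terms$parent[g] &
                             extant_gen != g]
      donors <- donors[!(terms$name[donors] %in%
                           terms$name[terms$parent == terms$parent[g]])]
      if (!length(donors)) next
      d <- donors[sample.int(length(donors), 1)]
      if (terms$name[d] != terms$name[g]) terms$name[g] <- terms$name[d]
    }
  }

  # species (and subspecies) under each genus
  for (k in seq_along(genus_rows)) {
    g <- genus_rows[k]
    role <- terms$role[g]
    for (j in seq_len(genus_target[k])) {
      sp_name <- paste(terms$name[g], namer$gen(FALSE))
      s <- add(sp_name, "species", g, role)
      terms$extinct[s] <- terms$extinct[g]
      if (!terms$extinct[g] && role %in% c("obo", "backbone") &&
          stats::runif(1) < params$subspecies_rate) {
        ss <- add(paste(sp_name, namer$gen(FALSE)), "subspecies", s, role)
        terms$subsp[ss] <- TRUE
      }
    }
  }

  # planted synonyms; `via` records the source file that will carry each
  syn <- data.frame(idx = integer(0), name = character(0),
                    scope = character(0), type = character(0),
                    via = character(0), stringsAsFactors = FALSE)
  plant <- function(idx, name, scope, type, via) {
    syn[nrow(syn) + 1L, ] <<- list(idx, name, scope, type, via)
  }
  for (i in seq_len(nrow(terms))) {
    role <- terms$role[i]
    rank <- terms$rank[i]
    via <- if (terms$extinct[i]) "fossil" else role
    species_like <- rank %in% c("species", "subspecies")
    syn_name <- function() {
      if (species_like) paste(namer$gen(TRUE), namer$gen(FALSE))
      else namer$gen(TRUE)
    }
    tax_ok <- via %in% c("obo", "backbone", "fossil") ||
      (via == "tabular" && rank == "species")
    if (tax_ok && stats::runif(1) < params$synonym_rate) {
      plant(i, syn_name(), "RELATED", "TAXONOMIC", via)
    }
    if (!terms$extinct[i] && species_like &&
        stats::runif(1) < params$commonname_rate) {
      plant(i, paste(namer$gen(FALSE), "fish"), "EXACT", "COMMONNAME", via)
    }
    if (via == "obo" && stats::runif(1) < params$misspelling_rate) {
      w <- misspell(terms$name[i], namer)
      if (!is.na(w)) plant(i, w, "EXACT", "MISSPELLING", via)
    }
  }

  # mixed families: extant families with extinct genera that the fossil
  # source also lists (as valid extant rows), plus an occasional fossil
  # synonym on them
  mixed <- integer(0)
  for (f in fam_rows[!terms$extinct[fam_rows]]) {
    kids <- which(terms$parent == f)
    if (any(terms$extinct[kids]) && stats::runif(1) < 0.5) {
      mixed <- c(mixed, f)
      if (stats::runif(1) < params$synonym_rate) {
        plant(f, namer$gen(TRUE), "RELATED", "TAXONOMIC", "fossil")
      }
    }
  }

  # junk fossil rows: trace material, invalid intermediates, parentless
  extinct_rows <- which(terms$extinct)
  junk <- data.frame(kind = character(0), name = character(0),
                     rank = character(0), parent_name = character(0),
                     child_name = character(0), stringsAsFactors = FALSE)
  addj <- function(kind, name, rank, parent_name, child_name = "") {
    junk[nrow(junk) + 1L, ] <<- list(kind, name, rank, parent_name,
                                     child_name)
  }
  if (length(extinct_rows)) {
    n_trace <- stats::rbinom(1, length(extinct_rows), params$trace_fraction)
    anchors <- extinct_rows[terms$rank[extinct_rows] %in%
                              c("family", "genus")]
    for (j in seq_len(if (length(anchors)) n_trace else 0L)) {
      a <- anchors[sample.int(length(anchors), 1)]
      addj("trace", namer$gen(TRUE), "genus", terms$name[a])
    }
    for (g in genus_rows[terms$extinct[genus_rows]]) {
      f <- terms$parent[g]
      if (terms$extinct[f] && stats::runif(1) < params$invalid_fraction) {
        addj("invalid", namer$gen(TRUE), "subfamily", terms$name[f],
             child_name = terms$name[g])
      }
    }
    n_pl <- stats::rbinom(1, length(extinct_rows),
                          params$parentless_fraction)
    for (j in seq_len(n_pl)) addj("parentless", namer$gen(TRUE), "genus", "")
  }

  graph <- truth_to_graph(terms, syn, vocab)
  expected <- build_expected(terms, syn, mixed, root)
  structure(list(graph = graph,
                 truth = list(terms = terms, synonyms = syn, junk = junk,
                              mixed = mixed, expected = expected,
                              root = root),
                 params = params),
            class = "sim_taxonomy")
}

# materialize the truth table as a taxonomy graph (ids GT:<idx>)
truth_to_graph <- function(terms, syn, vocab) {
  g <- taxonomy_graph(ontology = "ground-truth")
  ids <- make_term_id("GT", seq_len(nrow(terms)))
  for (i in seq_len(nrow(terms))) {
    s <- syn[syn$idx == i, , drop = FALSE]
    srec <- if (nrow(s)) {
      synonym_record(s$name, s$scope, s$type, "truth")
    } else empty_synonyms()
    t <- taxon_term(ids[i], terms$name[i],
                    parent = if (terms$parent[i] > 0) ids[terms$parent[i]]
                             else NA_character_,
                    synonyms = srec, xrefs = ids[i],
                    is_extinct = terms$extinct[i], source = "truth")
    g <- add_term(g, annotate_rank(t, terms$rank[i], vocab))
  }
  g
}

# The expected merge product, derived from the planted facts alone:
# subspecies demoted to typed synonyms, disused taxa obsolete with their
# valid children reattached at the root, junk rows absent. Terms are keyed
# by (name, parent name) so planted homonyms stay distinguishable.
build_expected <- function(terms, syn, mixed, root) {
  n <- nrow(terms)
  keep <- !terms$subsp
  obsolete <- terms$disused
  parent_name <- ifelse(terms$parent > 0,
                        terms$name[pmax(terms$parent, 1L)], "")
  reatt <- terms$parent > 0 & terms$disused[pmax(terms$parent, 1)] &
    !terms$disused
  parent_name[reatt] <- terms$name[root]
  parent_name[obsolete] <- ""

  key <- function(i) paste0(terms$name[i], "|", parent_name[i])
  keys <- vapply(seq_len(n), key, character(1))

  # synonym sets: planted synonyms plus demoted subspecies
  syn_out <- data.frame(key = keys[syn$idx], name = syn$name,
                        scope = syn$scope, type = syn$type,
                        stringsAsFactors = FALSE)
  # synonyms planted on a subspecies migrate to its species
  planted_on_subsp <- terms$subsp[syn$idx]
  if (any(planted_on_subsp)) {
    syn_out$key[planted_on_subsp] <-
      keys[pmax(terms$parent[syn$idx], 1L)][planted_on_subsp]
  }
  subsp_rows <- which(terms$subsp)
  if (length(subsp_rows)) {
    sp <- terms$parent[subsp_rows]
    syn_out <- rbind(syn_out, data.frame(
      key = keys[sp], name = terms$name[subsp_rows], scope = "NARROW",
      type = "SUBSPECIES", stringsAsFactors = FALSE))
  }

  # xref prefixes by role and backbone coverage
  specialist <- terms$role %in% c("obo", "tabular")
  clade_root <- terms$rank == "class" & specialist
  in_backbone <- !terms$extinct & !(terms$subsp & specialist) &
    (!specialist | clade_root | terms$rank %in% c("order", "species"))
  prefixes <- lapply(seq_len(n), function(i) {
    p <- character(0)
    if (in_backbone[i]) p <- c(p, "NCBI")
    if (terms$extinct[i]) p <- c(p, "PBDB")
    if (!terms$extinct[i] && terms$role[i] == "obo") p <- c(p, "TTO")
    if (!terms$extinct[i] && terms$role[i] == "tabular") p <- c(p, "AWEB")
    if (i %in% mixed) p <- c(p, "PBDB")
    sort_c(p)
  })
  # demoted subspecies leave their id as an xref on the species
  for (i in subsp_rows) {
    sp <- terms$parent[i]
    prefixes[[sp]] <- sort_c(union(prefixes[[sp]],
                                   if (terms$role[i] == "obo") "TTO"
                                   else "NCBI"))
  }

  exp_terms <- data.frame(
    key = keys[keep], name = terms$name[keep],
    parent_name = parent_name[keep], rank = terms$rank[keep],
    extinct = terms$extinct[keep], obsolete = obsolete[keep],
    stringsAsFactors = FALSE)
  exp_prefix <- prefixes[keep]
  names(exp_prefix) <- keys[keep]
  list(terms = exp_terms,
       synonyms = syn_out[syn_out$key %in% keys[keep], , drop = FALSE],
       prefixes = exp_prefix)
}
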