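# Rule-based enumeration of the random-order cap-binding-complex assembly
# network.  eIF4G (G) and mRNA (R) act as scaffolds; eIF4A (A), eIF4E (E),
# Ded1 (D) and Pab1 (P) are bivalent ligands with one G-facing and one
# R-facing site.  A complex carries at most one copy of each molecule and no
# direct G-R bond, the constraint set under which rule expansion with all
# four ligands yields 211 species and 872 reversible binding reactions.
#
# Internal species encoding: list(g = logical, r = logical,
#   lig = named character), where lig maps each ligand present in the
# complex to its bond state: "free" (free-monomer ligand only), "g" (bound
# to eIF4G only), "r" (bound to mRNA only) or "gr" (bridging both
# scaffolds).

#' Assembly-rule constraints
#'
#' The constraint set of the random-order binding scheme: at most one copy of
#' each molecule per complex and no direct scaffold-scaffold (eIF4G-mRNA)
#' bond. These are the only constraints the rule grammar supports; requesting
#' multi-copy complexes or direct scaffold bonds is rejected.
#'
#' @param single_copy Logical; must be `TRUE` (at most one copy of each
#'   molecule kind per complex).
#' @param scaffold_scaffold_bond Logical; must be `FALSE` (no direct G-R
#'   bond).
#' @return A named list of class `cap_constraints`.
#' @export
cap_constraints <- function(single_copy = TRUE, scaffold_scaffold_bond = FALSE) {
  if (!isTRUE(single_copy))
    stop("unsupported constraint: multi-copy complexes are not supported", call. = FALSE)
  if (!isFALSE(scaffold_scaffold_bond))
    stop("unsupported constraint: direct scaffold-scaffold bonds are not supported", call. = FALSE)
  structure(list(single_copy = TRUE, scaffold_scaffold_bond = FALSE),
            class = "cap_constraints")
}

.cap_ligands <- function(n_ligands) {
  if (!is.numeric(n_ligands) || length(n_ligands) != 1L || n_ligands < 0 ||
      n_ligands != round(n_ligands))
    stop("`n_ligands` must be a single non-negative integer", call. = FALSE)
  if (n_ligands > length(.cap_ligand_universe))
    stop("unsupported constraint: at most ", length(.cap_ligand_universe),
         " ligand kinds (", paste(.cap_ligand_universe, collapse = ", "),
         ") are defined", call. = FALSE)
  .cap_ligand_universe[seq_len(n_ligands)]
}

.cap_species <- function(g, r, lig) {
  list(g = g, r = r, lig = lig)
}

#' Canonical text label of a complex species
#'
#' Labels are deterministic and injective. A free monomer is written
#' `"G()"`, `"A()"`, etc. A multi-molecule complex lists its members in the
#' fixed order G, R, A, E, D, P, joined by `"."`; scaffolds appear bare and
#' each ligand is annotated with its bond state (`g`, `r` or `gr`), e.g.
#' `"G.R.E(gr)"` for eIF4E bridging both scaffolds.
#'
#' @param species An internal species object (as stored in a
#'   [generate_network()] result).
#' @return A character scalar.
#' @export
canonical_label <- function(species) {
  members <- c(if (species$g) "G", if (species$r) "R", names(species$lig))
  if (length(members) == 1L) {
    return(paste0(members, "()"))
  }
  parts <- character(0)
  for (m in .cap_member_order) {
    if (m %in% c("G", "R")) {
      if ((m == "G" && species$g) || (m == "R" && species$r)) parts <- c(parts, m)
    } else if (m %in% names(species$lig)) {
      parts <- c(parts, paste0(m, "(", species$lig[[m]], ")"))
    }
  }
  paste(parts, collapse = ".")
}

# number of bonds in a species
.cap_n_bonds <- function(species) {
  if (length(species$lig) == 0L) return(0L)
  sum(vapply(species$lig, function(s) switch(s, free = 0L, g = 1L, r = 1L, gr = 2L),
             integer(1)))
}

# all assignments of `states` over `ligs`, returned as a list of named
# character vectors over the ligands that are present (state != "absent")
.cap_state_grid <- function(ligs, states) {
  if (length(ligs) == 0L) return(list(character(0)))
  grid <- expand.grid(rep(list(states), length(ligs)), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    v <- unlist(grid[i, ], use.names = FALSE)
    names(v) <- ligs
    v[v != "absent"]
  })
}

#' Enumerate the species of the random-order assembly scheme
#'
#' Returns every connected complex over the scaffolds eIF4G and mRNA and the
#' first `n_ligands` ligands of (eIF4A, eIF4E, Ded1, Pab1) that satisfies the
#' single-copy and no-direct-G-R-bond constraints, including the free
#' monomers. With all four ligands this yields 211 species.
#'
#' Free monomers come first (G, R, then ligands in A, E, D, P order);
#' remaining species are sorted by canonical label (C locale), which fixes
#' all downstream indexing.
#'
#' @param n_ligands Number of ligand kinds (0-4).
#' @param constraints A [cap_constraints()] object.
#' @return A named list of species objects, names being canonical labels.
#' @export
enumerate_species <- function(n_ligands = 4, constraints = cap_constraints()) {
  stopifnot(inherits(constraints, "cap_constraints"))
  ligs <- .cap_ligands(n_ligands)

  free_monomers <- c(
    list(.cap_species(TRUE, FALSE, character(0)),
         .cap_species(FALSE, TRUE, character(0))),
    lapply(ligs, function(x) .cap_species(FALSE, FALSE, setNames("free", x)))
  )

  complexes <- list()
  # G-only complexes: G plus a non-empty ligand subset, all bound via g
  for (st in .cap_state_grid(ligs, c("absent", "g"))) {
    if (length(st) > 0L) complexes <- c(complexes, list(.cap_species(TRUE, FALSE, st)))
  }
  # R-only complexes
  for (st in .cap_state_grid(ligs, c("absent", "r"))) {
    if (length(st) > 0L) complexes <- c(complexes, list(.cap_species(FALSE, TRUE, st)))
  }
  # G&R complexes: connected iff at least one ligand bridges (state "gr")
  for (st in .cap_state_grid(ligs, c("absent", "g", "r", "gr"))) {
    if (any(st == "gr")) complexes <- c(complexes, list(.cap_species(TRUE, TRUE, st)))
  }

  labels_c <- vapply(complexes, canonical_label, character(1))
  complexes <- complexes[order(labels_c, method = "radix")]
  species <- c(free_monomers, complexes)
  names(species) <- vapply(species, canonical_label, character(1))
  species
}

#' Build the reaction network of the assembly scheme
#'
#' Emits every forward binding reaction of the four rule classes -- free
#' ligand onto a G-containing complex, free ligand onto an R-containing
#' complex, bimolecular bridging between a G-only and an R-only complex with
#' disjoint ligand content, and intramolecular ring closure of a
#' singly-tethered ligand -- plus exactly one reverse per forward. With all
#' four ligands the network has 211 species and 872 reversible pairs (1744
#' irreversible reactions).
#'
#' @inheritParams enumerate_species
#' @return An object of class `cap_network`: species list, reaction table
#'   (list-columns `reactants`/`products` hold species indices), and a
#'   `counts` record.
#' @export
generate_network <- function(n_ligands = 4, constraints = cap_constraints()) {
  species <- enumerate_species(n_ligands, constraints)
  labels <- names(species)
  idx <- setNames(seq_along(species), labels)
  lig_free_idx <- setNames(idx[paste0(.cap_ligands(n_ligands), "()")],
                           .cap_ligands(n_ligands))

  sp_idx_of <- function(sp) {
    i <- idx[[canonical_label(sp)]]
    if (is.null(i)) stop("internal consistency failure: product species not enumerated: ",
                         canonical_label(sp), call. = FALSE)
    i
  }

  rx_reactants <- list(); rx_products <- list()
  rx_class <- character(0); rx_param <- character(0)
  add_pair <- function(f_re, f_pr, f_cl, f_pa, r_re, r_pr, r_cl, r_pa) {
    k <- length(rx_class)
    rx_reactants[[k + 1L]] <<- f_re; rx_products[[k + 1L]] <<- f_pr
    rx_class[k + 1L] <<- f_cl; rx_param[k + 1L] <<- f_pa
    rx_reactants[[k + 2L]] <<- r_re; rx_products[[k + 2L]] <<- r_pr
    rx_class[k + 2L] <<- r_cl; rx_param[k + 2L] <<- r_pa
  }

  for (i in seq_along(species)) {
    sp <- species[[i]]
    # free ligand X binds the G site of a G-containing complex
    if (sp$g) {
      for (x in setdiff(.cap_ligands(n_ligands), names(sp$lig))) {
        prod_sp <- sp
        prod_sp$lig <- c(sp$lig[sp$lig != "free"], setNames("g", x))
        j <- sp_idx_of(prod_sp)
        add_pair(c(lig_free_idx[[x]], i), j, "bind_free_to_G", paste0("kon_G_", x),
                 j, c(lig_free_idx[[x]], i), "unbind_terminal", paste0("koff_G_", x))
      }
    }
    # free ligand X binds the R site of an R-containing complex
    if (sp$r) {
      for (x in setdiff(.cap_ligands(n_ligands), names(sp$lig))) {
        prod_sp <- sp
        prod_sp$lig <- c(sp$lig[sp$lig != "free"], setNames("r", x))
        j <- sp_idx_of(prod_sp)
        add_pair(c(lig_free_idx[[x]], i), j, "bind_free_to_R", paste0("kon_R_", x),
                 j, c(lig_free_idx[[x]], i), "unbind_terminal", paste0("koff_R_", x))
      }
    }
    # intramolecular ring closure of a singly-tethered ligand in a G&R complex
    if (sp$g && sp$r) {
      for (x in names(sp$lig)) {
        st <- sp$lig[[x]]
        if (st %in% c("g", "r")) {
          prod_sp <- sp
          prod_sp$lig[[x]] <- "gr"
          j <- sp_idx_of(prod_sp)
          kc <- if (st == "g") paste0("kc_R_", x) else paste0("kc_G_", x)
          add_pair(i, j, "ring_closure", kc,
                   j, i, "unbind_in_ring", paste0("koff_bridge_", x))
        }
      }
    }
  }

  # bimolecular bridging: G-only complex + R-only complex, disjoint ligand
  # content; a singly bound ligand of one partner binds the other scaffold
  g_only <- which(vapply(species, function(s) s$g && !s$r, logical(1)))
  r_only <- which(vapply(species, function(s) s$r && !s$g, logical(1)))
  for (i1 in g_only) {
    s1 <- species[[i1]]
    for (i2 in r_only) {
      s2 <- species[[i2]]
      if (length(intersect(names(s1$lig), names(s2$lig))) > 0L) next
      merge_lig <- function(bridge) {
        st <- c(s1$lig, s2$lig)
        st[[bridge]] <- "gr"
        st
      }
      for (x in names(s1$lig)) {  # X (bound g in s1) forms the X-R bond
        j <- sp_idx_of(.cap_species(TRUE, TRUE, merge_lig(x)))
        add_pair(c(i1, i2), j, "bridge_association", paste0("kon_R_", x),
                 j, c(i1, i2), "unbind_fission", paste0("koff_R_", x))
      }
      for (x in names(s2$lig)) {  # X (bound r in s2) forms the X-G bond
        j <- sp_idx_of(.cap_species(TRUE, TRUE, merge_lig(x)))
        add_pair(c(i1, i2), j, "bridge_association", paste0("kon_G_", x),
                 j, c(i1, i2), "unbind_fission", paste0("koff_G_", x))
      }
    }
  }

  n_rx <- length(rx_class)
  reactions <- data.frame(
    class = rx_class,
    rate_param = rx_param,
    reverse_of = as.integer(ifelse(seq_len(n_rx) %% 2L == 1L,
                                   seq_len(n_rx) + 1L, seq_len(n_rx) - 1L)),
    stringsAsFactors = FALSE
  )
  reactions$reactants <- rx_reactants
  reactions$products <- rx_products

  structure(list(
    species = species,
    labels = labels,
    reactions = reactions,
    n_ligands = as.integer(n_ligands),
    staged = FALSE,
    counts = list(n_species = length(species),
                  n_irreversible = n_rx,
                  n_reversible_pairs = n_rx %/% 2L)
  ), class = "cap_network")
}

#' Append the translation-stage reactions
#'
#' Adds the four stage species (43S preinitiation complex `S43`, elongating
#' ribosome `EL`, free 40S subunit `S40`, peptide `PEP`) and two irreversible
#' reactions: the fully assembled cap complex (all ligands bridging both
#' scaffolds) binds the 43S complex, producing an elongating ribosome and
#' the free forms of eIF4G and all ligands; and the elongating ribosome
#' dissociates into a free 40S subunit, a peptide and free mRNA. These two
#' steps let the assembly pathway reach a quasi-steady state with a
#' continuous translation flux. For the 4-ligand network this yields 215
#' species and 1746 reactions.
#'
#' @param network A `cap_network` from [generate_network()].
#' @return The augmented `cap_network` (with `staged = TRUE`).
#' @export
add_translation_stage <- function(network) {
  stopifnot(inherits(network, "cap_network"))
  if (isTRUE(network$staged))
    stop("translation stage already present", call. = FALSE)
  ligs <- .cap_ligands(network$n_ligands)
  full_label <- canonical_label(.cap_species(TRUE, TRUE, setNames(rep("gr", length(ligs)), ligs)))
  idx_full <- match(full_label, network$labels)
  if (is.na(idx_full))
    stop("fully assembled complex ", full_label, " absent from network", call. = FALSE)

  n0 <- length(network$species)
  stage <- setNames(seq_along(.cap_stage_species) + n0, .cap_stage_species)
  for (s in .cap_stage_species) network$species[[s]] <- structure(list(stage = s), class = "cap_stage_species")
  network$labels <- c(network$labels, .cap_stage_species)

  free_of <- function(m) match(paste0(m, "()"), network$labels)
  rx <- network$reactions
  rx2 <- data.frame(class = c("initiate_43S", "complete_elongation"),
                    rate_param = c("k_init", "k_elong"),
                    reverse_of = NA_integer_, stringsAsFactors = FALSE)
  rx2$reactants <- list(c(idx_full, stage[["S43"]]), stage[["EL"]])
  rx2$products <- list(
    c(stage[["EL"]], free_of("G"), vapply(ligs, free_of, integer(1))),
    c(stage[["S40"]], stage[["PEP"]], free_of("R")))
  network$reactions <- rbind(rx, rx2)

  network$staged <- TRUE
  network$idx_full <- idx_full
  network$idx_stage <- stage
  network$counts$n_species <- network$counts$n_species + 4L
  network$counts$n_irreversible <- network$counts$n_irreversible + 2L
  network
}

#' Composition matrix of a network
#'
#' Molecule-kind balance tokens per species: one column per scaffold/ligand
#' plus a shared `RIB` (ribosome) token carried by S43, EL and S40. The
#' elongating ribosome additionally carries one mRNA; the peptide has empty
#' composition, exempting peptide synthesis from balance checking.
#'
#' @param network A `cap_network`.
#' @return An integer matrix, species x tokens.
#' @export
species_composition <- function(network) {
  tokens <- c(.cap_scaffolds, .cap_ligands(network$n_ligands), "RIB")
  comp <- matrix(0L, nrow = length(network$species), ncol = length(tokens),
                 dimnames = list(network$labels, tokens))
  for (i in seq_along(network$species)) {
    sp <- network$species[[i]]
    if (inherits(sp, "cap_stage_species")) {
      comp[i, "RIB"] <- if (sp$stage %in% c("S43", "EL", "S40")) 1L else 0L
      if (sp$stage == "EL") comp[i, "R"] <- 1L
    } else {
      comp[i, "G"] <- as.integer(sp$g)
      comp[i, "R"] <- as.integer(sp$r)
      for (x in names(sp$lig)) comp[i, x] <- 1L
    }
  }
  comp
}

#' Check molecule-kind balance of every reaction
#'
#' @param network A `cap_network`.
#' @return Logical vector, one entry per reaction (TRUE = balanced).
#' @export
check_balance <- function(network) {
  comp <- species_composition(network)
  rx <- network$reactions
  vapply(seq_len(nrow(rx)), function(j) {
    lhs <- colSums(comp[rx$reactants[[j]], , drop = FALSE])
    rhs <- colSums(comp[rx$products[[j]], , drop = FALSE])
    all(lhs == rhs)
  }, logical(1))
}

#' Per-species summary table of a network
#'
#' @param network A `cap_network`.
#' @return A data frame with columns `label`, `n_members`, `n_bonds`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "cap_network"))
  n_members <- vapply(network$species, function(sp) {
    if (inherits(sp, "cap_stage_species")) 1L else as.integer(sp$g + sp$r + length(sp$lig))
  }, integer(1))
  n_bonds <- vapply(network$species, function(sp) {
    if (inherits(sp, "cap_stage_species")) 0L else .cap_n_bonds(sp)
  }, integer(1))
  data.frame(label = network$labels, n_members = n_members, n_bonds = n_bonds,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Network size record
#'
#' @param network A `cap_network`.
#' @return List with `n_species`, `n_irreversible`, `n_reversible_pairs`.
#' @export
network_counts <- function(network) {
  stopifnot(inherits(network, "cap_network"))
  network$counts
}

#' @export
print.cap_network <- function(x, ...) {
  cat("cap-binding assembly network (", x$n_ligands, " ligands",
      if (x$staged) ", translation stage added", ")\n", sep = "")
  cat("  species:     ", x$counts$n_species, "\n", sep = "")
  cat("  reactions:   ", x$counts$n_irreversible, " irreversible (",
      x$counts$n_reversible_pairs, " reversible binding pairs)\n", sep = "")
  invisible(x)
}
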