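# Independent brute-force oracle for the assembly network: grows the species
# set breadth-first from the free monomers by applying generic bond-forming
# moves to explicit molecule/bond graphs (no reuse of the package's
# state-vector representation), then counts species and distinct moves.

oracle_label <- function(cx) {
  paste(paste(sort(cx$members), collapse = ","),
        paste(sort(cx$bonds), collapse = ","), sep = "|")
}

# all complexes obtainable by forming one new ligand-scaffold bond, either
# inside `cx` (ring closure) or by merging `cx` with `other`
oracle_moves <- function(cx, other = NULL) {
  out <- list()
  if (is.null(other)) {  # intramolecular
    ligands <- setdiff(cx$members, c("G", "R"))
    for (x in ligands) for (s in intersect(c("G", "R"), cx$members)) {
      b <- paste(x, s, sep = "-")
      if (!(b %in% cx$bonds))
        out[[length(out) + 1L]] <- list(members = cx$members,
                                        bonds = c(cx$bonds, b))
    }
  } else {
    if (length(intersect(cx$members, other$members)) > 0L) return(out)
    members <- c(cx$members, other$members)
    bonds0 <- c(cx$bonds, other$bonds)
    for (pair in list(c(1, 2), c(2, 1))) {
      a <- list(cx, other)[[pair[1]]]; b2 <- list(cx, other)[[pair[2]]]
      for (x in setdiff(a$members, c("G", "R")))
        for (s in intersect(c("G", "R"), b2$members))
          out[[length(out) + 1L]] <- list(members = members,
                                          bonds = c(bonds0, paste(x, s, sep = "-")))
    }
  }
  out
}

# breadth-first closure from free monomers; returns species list and the
# number of distinct forward bond-forming moves
oracle_network <- function(n_ligands) {
  ligands <- c("A", "E", "D", "P")[seq_len(n_ligands)]
  species <- lapply(c("G", "R", ligands),
                    function(m) list(members = m, bonds = character(0)))
  names(species) <- vapply(species, oracle_label, character(1))
  frontier <- species
  while (length(frontier) > 0L) {
    fresh <- list()
    for (cx in frontier) {
      cands <- oracle_moves(cx)
      for (other in species) cands <- c(cands, oracle_moves(cx, other))
      for (p in cands) {
        lb <- oracle_label(p)
        if (is.null(species[[lb]]) && is.null(fresh[[lb]])) fresh[[lb]] <- p
      }
    }
    species <- c(species, fresh)
    frontier <- fresh
  }

  # distinct forward moves over the closed species set
  n_forward <- 0L
  seen <- new.env(hash = TRUE)
  for (i in seq_along(species)) {
    for (p in oracle_moves(species[[i]]))
      assign(paste("intra", oracle_label(species[[i]]), oracle_label(p)), TRUE, seen)
    for (j in seq_along(species)) {
      if (j <= i) next
      for (p in oracle_moves(species[[i]], species[[j]])) {
        key <- paste("inter", oracle_label(species[[i]]), oracle_label(species[[j]]),
                     oracle_label(p))
        assign(key, TRUE, seen)
      }
    }
  }
  n_forward <- length(ls(seen))

  n_bonds_total <- sum(vapply(species, function(s) length(s$bonds), integer(1)))
  list(n_species = length(species),
       n_forward = n_forward,
       n_reverse = n_bonds_total)  # one dissociation per existing bond
}

# hand-written mass-action ODEs for the 1-ligand staged toy model
# state: named vector over G(), R(), A(), G.A(g), G.R.A(gr), R.A(r),
#        S43, EL, S40, PEP (S43/S40 fixed)
toy_rhs <- function(x, p) {
  v <- c(p[["kon_G_A"]] * x[["A()"]] * x[["G()"]],
         p[["koff_G_A"]] * x[["G.A(g)"]],
         p[["kon_R_A"]] * x[["A()"]] * x[["R()"]],
         p[["koff_R_A"]] * x[["R.A(r)"]],
         p[["kon_R_A"]] * x[["G.A(g)"]] * x[["R()"]],
         p[["koff_R_A"]] * x[["G.R.A(gr)"]],
         p[["kon_G_A"]] * x[["R.A(r)"]] * x[["G()"]],
         p[["koff_G_A"]] * x[["G.R.A(gr)"]],
         p[["k_init"]] * x[["G.R.A(gr)"]] * x[["S43"]],
         p[["k_elong"]] * x[["EL"]])
  dx <- c(
    "G()" = -v[1] + v[2] - v[7] + v[8] + v[9],
    "R()" = -v[3] + v[4] - v[5] + v[6] + v[10],
    "A()" = -v[1] + v[2] - v[3] + v[4] + v[9],
    "G.A(g)" = v[1] - v[2] - v[5] + v[6],
    "G.R.A(gr)" = v[5] - v[6] + v[7] - v[8] - v[9],
    "R.A(r)" = v[3] - v[4] - v[7] + v[8],
    "S43" = 0, "EL" = v[9] - v[10], "S40" = 0, "PEP" = v[10])
  dx[names(x)]
}

# fixed-step classic Runge-Kutta integration of the toy ODEs
toy_rk4 <- function(x0, p, t_end, dt) {
  x <- x0
  steps <- round(t_end / dt)
  for (i in seq_len(steps)) {
    k1 <- toy_rhs(x, p)
    k2 <- toy_rhs(x + dt / 2 * k1, p)
    k3 <- toy_rhs(x + dt / 2 * k2, p)
    k4 <- toy_rhs(x + dt * k3, p)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# shared fixtures
toy_network_staged <- function(n_ligands = 1) {
  add_translation_stage(generate_network(n_ligands))
}
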