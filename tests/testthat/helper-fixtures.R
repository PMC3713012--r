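# Small in-code fixtures shared across test files.

# A molecule from bare coordinates; one residue per atom unless stated.
make_mol <- function(id, xyz, radius = 1.7, charge = 0,
                     names = NULL, residue_index = NULL,
                     frame_tag = "test") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (n == 0L) {
    atoms <- data.frame(element = character(0), name = character(0),
                        residue_name = character(0),
                        residue_index = integer(0), chain_id = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        vdw_radius = numeric(0), partial_charge = numeric(0),
                        stringsAsFactors = FALSE)
    return(new_molecule(id, atoms, frame_tag = frame_tag))
  }
  if (is.null(names)) names <- paste0("C", seq_len(n))
  if (is.null(residue_index)) residue_index <- seq_len(n)
  atoms <- data.frame(
    element = "C", name = names, residue_name = "UNK",
    residue_index = residue_index, chain_id = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw_radius = radius, partial_charge = charge,
    stringsAsFactors = FALSE)
  new_molecule(id, atoms, frame_tag = frame_tag)
}

# A tripeptide-like molecule with backbone + side-chain atoms.
make_peptide <- function(id, shift = c(0, 0, 0), frame_tag = "test") {
  base <- expand.grid(name = c("N", "CA", "C", "O", "CB"), res = 1:3)
  n <- nrow(base)
  xyz <- cbind(3 * base$res + as.integer(factor(base$name)) * 0.7,
               rep(c(0, 1, 0.5, -0.5, 1.5), 3),
               rep(c(0.2, 0, -0.3, 0.4, 1.0), 3))
  xyz <- sweep(xyz, 2, shift, "+")
  atoms <- data.frame(
    element = substr(as.character(base$name), 1, 1),
    name = as.character(base$name), residue_name = "ALA",
    residue_index = base$res, chain_id = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw_radius = 1.7, partial_charge = 0, stringsAsFactors = FALSE)
  new_molecule(id, atoms, frame_tag = frame_tag)
}

# Wrap a bare value vector in a ScalarField on a given grid.
make_field <- function(values, grid, kind = "shape") {
  crossreact3d:::new_scalar_field(grid, kind, values)
}

tiny_grid <- function(n = 5, spacing = 1) {
  grid_spec(c(0, 0, 0), spacing, c(n, n, n))
}

# Small descriptor pool with a planted perfect predictor in column 1.
planted_pool <- function(n = 12, p = 8, seed = 42) {
  withr::with_seed(seed, {
    s <- sort(runif(n, 0.95, 1))
    pool <- matrix(runif(n * p, 0.9, 1), n, p)
    pool[, 1] <- s
    rownames(pool) <- sprintf("m%02d", seq_len(n))
    colnames(pool) <- c("shape|ref", sprintf("col%d", seq_len(p - 1)))
    act <- 80 * s^40 - 20
    names(act) <- rownames(pool)
    list(pool = pool, activities = act, planted = "shape|ref")
  })
}
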