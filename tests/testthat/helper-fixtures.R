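# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; nothing is read from disk except
# files the tests themselves write.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, alt = "", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  nm <- if (nchar(trimws(name)) >= 4) substr(name, 1, 4)
        else sprintf(" %-3s", trimws(name))
  sprintf("ATOM  %5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resname, chain, resno, x, y, z, occ, 0, element)
}

write_tiny_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# five-residue peptide fixture; residue `skip_ca` gets no CA atom
peptide_pdb_lines <- function(n = 5, skip_ca = integer(0)) {
  out <- character(0)
  s <- 0
  for (r in seq_len(n)) {
    s <- s + 1
    out <- c(out, pdb_line(s, "N", "ALA", "A", r, r * 3.8, 0, 0, element = "N"))
    if (!r %in% skip_ca) {
      s <- s + 1
      out <- c(out, pdb_line(s, "CA", "ALA", "A", r, r * 3.8 + 1, 0.5, 0))
    }
  }
  out
}

random_calpha <- function(m, seed = 1, spread = 15) {
  set.seed(seed)
  calpha_model(
    data.frame(chain = "A", resno = seq_len(m), resname = "ALA"),
    matrix(runif(3 * m, 0, spread), ncol = 3))
}

# independent numerical Hessian of the harmonic network energy
# E = 1/2 sum_ij k_ij (r_ij - r0_ij)^2 by central finite differences
numeric_hessian <- function(network, h = 1e-4) {
  e <- network$edges
  energy <- function(xflat) {
    X <- matrix(xflat, ncol = 3, byrow = TRUE)
    d <- sqrt(rowSums((X[e$j, , drop = FALSE] - X[e$i, , drop = FALSE])^2))
    0.5 * sum(e$k * (d - e$r0)^2)
  }
  x0 <- as.vector(t(network$xyz))
  n <- length(x0)
  H <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in a:n) {
    xa <- xb <- xc <- xd <- x0
    xa[a] <- xa[a] + h; xa[b] <- xa[b] + h
    xb[a] <- xb[a] + h; xb[b] <- xb[b] - h
    xc[a] <- xc[a] - h; xc[b] <- xc[b] + h
    xd[a] <- xd[a] - h; xd[b] <- xd[b] - h
    H[a, b] <- H[b, a] <-
      (energy(xa) - energy(xb) - energy(xc) + energy(xd)) / (4 * h^2)
  }
  H
}

# dense Monte-Carlo SASA oracle for a set of spheres (radius incl. probe)
mc_sasa <- function(centers, radii_ext, n_mc = 1e5, seed = 7) {
  set.seed(seed)
  total <- 0
  for (i in seq_len(nrow(centers))) {
    u <- matrix(rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * radii_ext[i], 2, centers[i, ], `+`)
    exposed <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(centers))[-i]) {
      d2 <- rowSums(sweep(p, 2, centers[j, ])^2)
      exposed <- exposed & d2 > radii_ext[j]^2
    }
    total <- total + 4 * pi * radii_ext[i]^2 * mean(exposed)
  }
  total
}

# brute-force minimum-image distance via explicit image enumeration
brute_min_image <- function(p, q, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- p - (q + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# single-chain atom model from explicit atom rows (list of lists)
make_atoms <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r$chain, resno = r$resno, ins = "",
               resname = r$resname, atom = r$atom, element = r$element,
               altloc = "", occ = 1,
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3])))
  atom_model(df)
}
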