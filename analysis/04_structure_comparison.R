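#!/usr/bin/env Rscript
# Structural-comparison arm, run on synthetic stand-ins (no deposited
# coordinates are bundled): (1) the Kabsch-with-rejection superposition
# protocol applied to two copies of a ~300-residue chain differing by a
# rigid motion, a few missing residues and 0.4 A-scale coordinate noise,
# the regime of comparing two independent refinements of one protein;
# (2) van der Waals contact analysis of the PS sulfur pocket in the
# synthetic strand augmented with arginine/lysine side-chain fragments.

suppressMessages(library(psbind))
dir.create("results", showWarnings = FALSE)

# --- superposition ---------------------------------------------------------
set.seed(8)
aas <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
n <- 300
t_idx <- seq_len(n)
xyz <- cbind(10 * cos(t_idx / 3) + 0.3 * cumsum(rnorm(n)),
             10 * sin(t_idx / 3) + 0.3 * cumsum(rnorm(n)),
             1.5 * t_idx)
ref <- structure_model(data.frame(
  serial = t_idx, name = "CA", altloc = "", resname = aas[(t_idx * 7) %% 20 + 1],
  chain = "A", resno = t_idx, insert = "",
  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
  occupancy = 1, b_factor = 20, element = "C"), "synthetic_ref")

mob <- ref
mob$atoms <- mob$atoms[!(mob$atoms$resno %in% c(3, 150, 151, 299)), ]
theta <- 0.7
R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
m_xyz <- as.matrix(mob$atoms[, c("x", "y", "z")]) %*% t(R)
m_xyz <- sweep(m_xyz, 2, c(15, -8, 3), "+") +
  matrix(rnorm(length(m_xyz), 0, 0.4 / sqrt(3)), ncol = 3)
mob$atoms[, c("x", "y", "z")] <- m_xyz

pairs <- match_calpha(ref, mob, "A", "A")
sup <- superpose(pairs)
cat(sprintf("superposition: %d residues paired by sequence alignment\n", pairs$n))
cat(sprintf("  rmsd %.2f A over %d C-alpha atoms (%d rejected over %d cycles)\n",
            sup$rmsd, sup$n_atoms, length(sup$rejected),
            length(sup$rmsd_history)))
jsonlite::write_json(
  list(n_paired = pairs$n, rmsd = sup$rmsd, n_atoms = sup$n_atoms,
       n_rejected = length(sup$rejected),
       rotation = sup$rotation, translation = sup$translation),
  "results/superposition.json", auto_unbox = TRUE, digits = NA)

# --- PS sulfur contact pocket ---------------------------------------------
strand <- build_ps_strand(fixture_spec(15, rep("Rp", 14)))
# place Arg/Lys side-chain carbons at van der Waals distance of the last
# linkage's sulfur (the terminal-PS pocket scenario)
s_row <- strand$atoms[strand$atoms$element == "S" &
                        strand$atoms$resno == 15, ][1, ]
s_pos <- c(s_row$x, s_row$y, s_row$z)
prot <- do.call(rbind, lapply(seq_len(4), function(i) {
  ang <- i * 1.6
  off <- c(3.7 * cos(ang), 3.7 * sin(ang), 0.4 * (-1)^i)
  data.frame(serial = 1000 + i, name = c("CD", "CZ", "CE", "CD")[i],
             altloc = "", resname = c("ARG", "ARG", "LYS", "LYS")[i],
             chain = "P", resno = c(205, 205, 206, 206)[i], insert = "",
             x = s_pos[1] + off[1], y = s_pos[2] + off[2],
             z = s_pos[3] + off[3],
             occupancy = 1, b_factor = 25, element = "C")
}))
model <- structure_model(rbind(strand$atoms, prot), "synthetic_complex")
contacts <- find_contacts(model, select_atoms(model, chain = "A"),
                          select_atoms(model, chain = "P"))
pocket <- summarize_pocket(contacts, model)
cat("\nPS sulfur pocket (residues ranked by hydrophobic contacts):\n")
print(pocket, row.names = FALSE)
write.csv(pocket, "results/contact_pocket.csv", row.names = FALSE)
cat("written: results/superposition.json, results/contact_pocket.csv\n")
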