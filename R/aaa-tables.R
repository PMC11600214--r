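# Shared amino-acid tables (one/three-letter codes, residue
# volumes, polar/hydrophobic partition).  Loaded first.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

# Mean residue volumes (A^3, Zamyatnin-style table); the effective
# C-alpha sphere radius is the radius of the equal-volume sphere.
AA_VOLUME <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0
)

# Fixed polar / hydrophobic partition used to split SASA.  Every residue
# belongs to exactly one class, so total = polar + hydrophobic holds by
# construction.
AA_HYDROPHOBIC <- c("A", "V", "L", "I", "P", "F", "M", "W", "G", "C")
AA_POLAR <- setdiff(names(AA_VOLUME), AA_HYDROPHOBIC)

AA20 <- sort(names(AA_VOLUME))
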