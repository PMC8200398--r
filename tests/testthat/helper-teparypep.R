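# The published recombinant lectin construct (255 aa, leading EAEA
# propeptide remnant and C-terminal His tag), as printed line by line.
LECTIN_SEQ <- paste0(
  "EAEAAASANDISFNFQRFNETNLILQGDASVSSSGQLRLTNLNDNGEPTLSSLGRAFYSTPIQI",
  "WDSTTGAVASFATSFTFNIRVPNNAGPADGLAFALVPVGSKPKDRGGLLGLFDGSDSKAHT",
  "VAVEFDTLYNRDWDPRERHIGIDVNSIKSIKTTPWDFVNGEDAEVLITYDSSTKLLVASLVYP",
  "SQKTSFIVSDTVDLKSVLPEWVSVGFSATSGISKGNVETNDLLSWSFASKLSDGTTSEGLNHH",
  "HHHH"
)

# The published multiset of 2-5-mers released by the GI digest (45
# peptides, AF and SIK each twice), in published score order.
PUBLISHED_2_5 <- c(
  "PEW", "VSVGF", "PSQK", "TTPW", "ATSF", "ITY", "TSF", "DISF", "VY",
  "SW", "VASL", "TF", "DSSTK", "VPN", "IL", "VETN", "GEPTL", "DW",
  "SF", "SVL", "QR", "PK", "AF", "AF", "SIK", "SIK", "IR", "DPR",
  "SSL", "ETN", "AH", "DR", "GR", "ER", "DF", "ASK", "TN", "DTL",
  "GGL", "VN", "GN", "DN", "AL", "GL", "DL"
)

# Union cut-after set of the calibrated GI panel.
GI_CUT_SET <- c("F", "L", "W", "Y", "K", "R", "N", "H")

# Write FASTA text to a temp file and return the path.
local_fasta <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = env)
  writeLines(lines, path)
  path
}

# A single-enzyme panel, convenient in small digestion tests.
one_rule_panel <- function(p1, excl = character(), name = "test") {
  enzyme_panel(cleavage_rule("test_enzyme", NA_character_, p1, excl),
               name = name)
}
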