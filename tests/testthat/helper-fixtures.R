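# shared fixtures: tiny sequences and synthetic TM constructs, all built in
# code at test time

ps <- function(id, residues) protein_sequence(id, residues)

blosum62 <- mipscan:::substitution_matrix("BLOSUM62")

rec_ids <- function(recs) vapply(recs, function(s) s$id, character(1L))

# k hydrophobic blocks (poly-I, len tm) separated/flanked by poly-S loops
tm_block_seq <- function(id = "blocks", k = 6L, tm = 21L, loop = 12L) {
  body <- paste0(strrep("S", loop),
                 paste(rep(paste0(strrep("I", tm), strrep("S", loop)), k),
                       collapse = ""))
  protein_sequence(id, body)
}

# planted TM starts for tm_block_seq
tm_block_starts <- function(k = 6L, tm = 21L, loop = 12L) {
  loop + (seq_len(k) - 1L) * (tm + loop) + 1L
}

# random sequence over the 20 standard residues
random_seq <- function(id, n, seed) {
  with_seed_t(seed, protein_sequence(id, paste(sample(mipscan:::AA_STANDARD,
                                                      n, replace = TRUE),
                                               collapse = "")))
}

# local seeding that restores RNG state
with_seed_t <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
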