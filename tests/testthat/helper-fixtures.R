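# Shared fixture builders: everything is generated in code at test time.

# Write a FASTA file into tempdir; returns the path.
tmp_fasta <- function(lines, name = "fixture.fa") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# Random U-centered fragment of odd length w (uniform background).
random_fragment <- function(w) {
  chars <- sample(c("A", "C", "G", "U"), w, replace = TRUE)
  chars[(w + 1) %/% 2] <- "U"
  paste(chars, collapse = "")
}

# Small balanced labeled dataset of random fragments.
random_dataset <- function(n_per_class = 10, w = 9, seed = 1) {
  withr::with_seed(seed, {
    frags <- replicate(2 * n_per_class, random_fragment(w))
  })
  fragment_dataset(frags,
                   label = rep(c("positive", "negative"), each = n_per_class))
}

# FASTA-pair files for a labeled dataset; returns c(pos=, neg=).
dataset_fasta_pair <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pos <- file.path(dir, "pos.fa"); neg <- file.path(dir, "neg.fa")
  write_fasta(subset_dataset(ds, which(ds$label == "positive")), pos)
  write_fasta(subset_dataset(ds, which(ds$label == "negative")), neg)
  c(pos = pos, neg = neg)
}
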