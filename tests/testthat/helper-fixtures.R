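# Shared fixtures. Expensive artifacts (the pretrained checkpoint, the
# synthetic benchmark and its fine-tuning runs) are computed once per test
# session and memoised here; the study conditions they encode are fixed and
# never vary per test.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

small_molecules <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1O",
                     "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CN1CCC[C@H]1c1cccnc1", "C")

# pretraining at the fixed study conditions: full fixture corpus,
# d_hidden 64, batch 32, 20 epochs, seed 0
get_pretrained <- function() {
  memo("pretrained", function() {
    state <- encoder_state(d_hidden = 64, depth = 3, d_proj = 64, seed = 0)
    pretrain(load_fixture_corpus(), state,
             contrastive_config(temperature = 0.1, batch_size = 32,
                                epochs = 20, seed = 0))
  })
}

# synthetic hydroxyl-presence benchmark: n = 800, seed 1, scaffold split
get_synth_task <- function() {
  memo("synth_task", function() {
    ds <- generate_dataset(synthetic_task_spec("presence", "hydroxyl",
                                               n_molecules = 800, seed = 1))
    list(dataset = ds, split = scaffold_split(ds))
  })
}

synth_finetune_config <- function(...) {
  finetune_config(epochs = 10, patience = 5, batch_size = 64, ...)
}

# five independent fine-tuning runs of the full model (seeds 0..4)
get_full_fit <- function() {
  memo("full_fit", function() {
    task <- get_synth_task()
    finetune(task$dataset, checkpoint = get_pretrained(),
             config = synth_finetune_config(), split = task$split, seeds = 0:4)
  })
}

# matching runs with the prompt channel ablated
get_noprompt_fit <- function() {
  memo("noprompt_fit", function() {
    task <- get_synth_task()
    finetune(task$dataset, checkpoint = get_pretrained(),
             config = synth_finetune_config(no_fg_prompt = TRUE),
             split = task$split, seeds = 0:4)
  })
}

test_auc_per_seed <- function(fit) {
  m <- tidy(fit)
  vapply(split(m$value, m$seed), mean, numeric(1))
}

# independent brute-force ROC-AUC: fraction of (positive, negative) pairs
# ranked correctly, ties counted half
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# independent NT-Xent enumeration: builds the full 2N x 2N cosine matrix and
# sums the per-anchor terms explicitly
ntxent_enumeration <- function(z, zt, tau) {
  Z <- rbind(z, zt)
  N <- nrow(z)
  n2 <- 2 * N
  cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  S <- matrix(0, n2, n2)
  for (i in seq_len(n2)) {
    for (k in seq_len(n2)) S[i, k] <- cosine(Z[i, ], Z[k, ])
  }
  losses <- numeric(n2)
  for (i in seq_len(n2)) {
    j <- if (i <= N) i + N else i - N
    denom <- 0
    for (k in seq_len(n2)) {
      if (k != i) denom <- denom + exp(S[i, k] / tau)
    }
    losses[i] <- -log(exp(S[i, j] / tau) / denom)
  }
  mean(losses)
}

# reindex the atoms (and directed-edge order) of an atom graph
permute_atom_graph <- function(g, atom_perm, edge_perm = NULL) {
  pos <- match(seq_len(g$n_atoms), atom_perm)
  g$atom_features <- g$atom_features[atom_perm, , drop = FALSE]
  g$directed_bonds$src <- pos[g$directed_bonds$src]
  g$directed_bonds$dst <- pos[g$directed_bonds$dst]
  if (!is.null(edge_perm)) {
    g$directed_bonds <- g$directed_bonds[edge_perm, , drop = FALSE]
    g$bond_features <- g$bond_features[edge_perm, , drop = FALSE]
    g$rev <- match(g$rev[edge_perm], edge_perm)
  }
  g
}

permute_fragment_graph <- function(fg, perm) {
  pos <- match(seq_along(fg$fragments), perm)
  fg$fragments <- fg$fragments[perm]
  fg$fragment_features <- fg$fragment_features[perm, , drop = FALSE]
  fg$reaction_edges$u <- pos[fg$reaction_edges$u]
  fg$reaction_edges$v <- pos[fg$reaction_edges$v]
  fg
}
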