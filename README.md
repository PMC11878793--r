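# fragprompt

Self-supervised molecular representation learning with
chemistry-preserving augmentations, plus interpretable functional-group
prompts for downstream property prediction — in R, for cheminformatics and
drug-discovery researchers who want a label-efficient property predictor
that can say *which substructures drove a prediction*.

## The method

Contrastive pretraining of molecular graph encoders usually builds its
second "view" of a molecule by corrupting the graph (masking atoms,
deleting bonds). That destroys the chemical environment it is supposed to
represent. Here the second view is the molecule's **BRICS
fragment-reaction graph**: bonds matching the 16 retrosynthetic BRICS link
rules are cleaved, each resulting fragment becomes a node (featurized by
MACCS keys, element counts, TPSA, and H-bond donor/acceptor counts), and
each cleaved bond becomes an edge labelled with its link-class pair. Both
views describe the same, unaltered chemistry.

A directed-edge message-passing encoder *f* embeds the atom graph *G* and
a fragment-attention encoder *f̃* embeds the fragment graph *G̃*;
projection heads *g*, *g̃* map both to a latent space where the NT-Xent
objective

> ℓᵢ = −log [ exp(sim(z_Gᵢ, z_G̃ᵢ)/τ) / Σ_{k≠i} exp(sim(z_Gᵢ, z_k)/τ) ],  τ = 0.1

pulls the two views of each molecule together against all in-batch
negatives (sim = cosine).

For fine-tuning, a learnable embedding table over **82 named
functional-group SMARTS patterns** supplies prompts: each match Vᵢ in a
molecule is fused with the sum and max of its member atoms' encoder
embeddings, fĝᵢ = σ(W·[fgᵢ; Σ_{v∈Vᵢ} h_v; max_{v∈Vᵢ} h_v]), and a
learnable task token fg₀ attends over {fg₀, fĝ₁, …, fĝ_m} by
self-attention. Row 0 of the output is the prompt; the prediction head
reads [h_G; α·prompt]. The task token's softmax weights over the matches
are the model's per-group attribution report.

## Worked example

```r
library(fragprompt)

corpus <- load_fixture_corpus()                  # 240 curated molecules
state  <- encoder_state(d_hidden = 64, seed = 0)
pre    <- pretrain(corpus, state,
                   contrastive_config(batch_size = 32, epochs = 20, seed = 0))
pre
#> <pretrain_result> 20 epochs; first loss 8.7294, final loss 2.5471

ds  <- generate_dataset(synthetic_task_spec("presence", "hydroxyl",
                                            n_molecules = 800, seed = 1))
fit <- finetune(ds, checkpoint = pre,
                config = finetune_config(epochs = 10, patience = 5),
                seeds = 0:2)
glance(fit)
#> # A tibble: 1 × 4
#>   metric   mean    sd n_runs
#>   <chr>   <dbl> <dbl>  <int>
#> 1 roc_auc     1     0      3

predict(fit, c("CCO", "c1ccccc1"))
#> # A tibble: 2 × 2
#>   smiles   .pred_label
#>   <chr>          <dbl>
#> 1 CCO          0.998
#> 2 c1ccccc1     0.00986

explain(fit, "CC(O)c1ccccc1", weight_threshold = 0.1)
#> # A tibble: 2 × 4
#>   smiles        fg_name           atom_indices weight
#>   <chr>         <chr>             <chr>         <dbl>
#> 1 CC(O)c1ccccc1 hydroxyl          2             0.641
#> 2 CC(O)c1ccccc1 secondary alcohol 0;1;2         0.122
```

The pretraining loss falls from 8.73 to 2.55 over 20 epochs on the fixture
corpus; the fine-tuned model separates hydroxyl-bearing from hydroxyl-free
molecules perfectly on scaffold-held-out test molecules (ROC-AUC 1.0 over
three independent runs), predicts ethanol positive (0.998) and benzene
negative (0.010), and attributes the prediction for
1-phenylethanol chiefly to its hydroxyl group (mean task-token attention
0.64, with the overlapping secondary-alcohol match second at 0.12).

A command-line interface wraps the same functions
(`pretrain`, `finetune`, `predict`, `explain`, `make-fixtures`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fragprompt.R", package = "fragprompt"))')" \
    finetune --data task.csv --task classification --out model/
```

## Package layout

- `R/` — featurization and graph building, scaffold splitting, metrics,
  the tape-based training core, both encoders, the contrastive loop, the
  functional-group prompt module, fine-tuning/explain, synthetic data,
  CLI.
- `inst/extdata/` — the 82-entry functional-group table and the fixture
  corpus (plain text).
- `inst/python/mol_helper.py` — batched RDKit helper (SMILES parsing,
  BRICS, SMARTS matching, descriptors, recombination).
- `vignettes/fragprompt-methods.Rmd` — the model, its assumptions,
  numerical choices, and limitations.
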