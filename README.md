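# echonet

Entropy-based detection of echo chambers in retweet and URL-sharing
networks.

## What it does, and for whom

`echonet` is for computational social scientists and network analysts who
have a table of social-media posts (tweets and retweets, with author ids,
verified flags and shared URLs) and want a *statistically principled*
answer to the question "which users sit in an echo chamber?" — without
hand-picking topics, hashtags or source lists. The method is agnostic to
content: everything is inferred from who retweets whom and who shares
which URL, benchmarked against a maximum-entropy null model so that
anything explainable by sheer activity levels is discarded as noise.

Operationally, an echo chamber is a set of ≥ 2 users who simultaneously

1. belong to the same **news engagement community** (NEC): their URL
   co-sharing is significantly richer than the null model predicts;
2. belong to the same **discursive community** (DiCo): they inherit,
   through the retweet network, the community labels of verified users
   whose audiences overlap significantly;
3. are connected, even indirectly, through retweets (a weakly connected
   component).

## The model in brief

Both detection paths validate a bipartite network against the Bipartite
Configuration Model (BiCM), the maximum-entropy ensemble constrained to
the observed degree sequences. Entropy maximization factorizes the graph
probability into independent links

$$p_{i\alpha} = \frac{e^{-(\theta_i+\eta_\alpha)}}{1+e^{-(\theta_i+\eta_\alpha)}},
  \qquad
  \langle k_i\rangle = k_i^*,\ \ \langle h_\alpha\rangle = h_\alpha^* ,$$

with multipliers fixed by likelihood maximization. For each node pair the
observed co-occurrence $V^*_{ij}=\sum_\alpha b_{i\alpha}b_{j\alpha}$ is
tested against its Poisson–binomial null (success probabilities
$p_{i\alpha}p_{j\alpha}$, exact dynamic-programming tail), with
Benjamini–Hochberg FDR control over all $\binom{N}{2}$ pairs. Validated
pairs form the monopartite projection; best-of-N shuffled Louvain finds
communities there; a two-phase majority label propagation extends the
verified communities to all users over the retweet network. See
`vignettes/echo-chamber-detection.Rmd` for the full account.

## Worked example

The package ships a seeded generator that plants two discursive blocks,
one NEC of 8 heavy URL-sharers and a retweet-connected chamber:

```r
library(echonet)

sim  <- generate_dataset(synthetic_config(seed = 42))
d    <- sim$dataset
d
#> echo_dataset: 3105 posts (2565 retweets, 540 with URLs), 814 users (20 verified)

dico <- detect_dico(d, n_shuffles = 100, seed = 1)
dico$tallies
#>   dico users tweets retweets users_url tweets_url retweets_url
#> 1    1   397    266     1279       259        266            0
#> 2    2   404    261     1286       261        261            0

nec  <- detect_nec(d, n_shuffles = 100, seed = 2)
nec$tallies
#>   nec users url_shares
#> 1   0     8        139

rt <- build_retweet_network(d)
ec <- detect_echo_chambers(dico, nec, rt)
ec
#> echo_chambers: 1 chambers, 0 users excluded
#>   chamber 0 (NEC 0, DiCo 1): 8 members, clustering 0.120
```

Reading the numbers: the two planted blocks are recovered as DiCos 1 and 2
(397 and 404 labeled users); exactly the 8 planted users survive the
projection validation and form NEC 0; all 8 share DiCo 1 and are retweet-
connected, so they form one echo chamber whose members cluster far more
than the background (average local clustering 0.120 vs 0.0024 for the
host DiCo at large, via `average_clustering(rt, dico_members)`). Trust tallies for the chamber show its news diet:

```r
tt <- tally_trust(d, setNames(rep("echo_chamber", 8), ec$chambers[[1]]$members),
                  sim$trust_labels)
tt[1, c("group", "T", "N", "UNC", "p_N")]
#>          group T   N UNC       p_N
#> 1 echo_chamber 4 132   3 0.9496403
```

The planted NEC pool points at an untrustworthy domain, and the tally
shows it: 95% of the chamber's shares are label N.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/echonet.R", package = "echonet"))')" \
  run --posts posts.jsonl --alpha 0.05 --shuffles 1000 --seed 1 \
  --connectivity nec_induced --trust-labels labels.csv --out outdir
```

Subcommands `dico`, `nec`, `echo`, `report` run individual stages; a
`--config file` of `key=value` lines mirrors every flag. Outputs: GraphML +
edge-list CSV for graphs, JSON for partitions and the run report, and a
`manifest.json` with per-file checksums (identical configs give identical
checksums).

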