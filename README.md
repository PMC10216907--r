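# rsgnn — ranking node spreading influence with a relationship-strength GNN

Who spreads best? In epidemiology, viral marketing and network robustness,
the practical question is which nodes of a contact network would seed the
largest outbreaks. `rsgnn` answers it with a small trainable graph neural
network whose ground truth is the epidemic process itself: each node's
influence label is the mean final outbreak size of discrete-time SIR
(susceptible–infected–recovered) epidemics seeded at that node.

## The method in brief

* **Features.** Two structural indicators per node — the degree $k(u)$ and
  the mean neighbour degree $\bar k(u)$ — fused by the entropy weight
  method into a basic feature
  $B(u) = \omega_1 k(u) + \omega_2 \bar k(u)$, where
  $\omega_1 = \frac{1-H_k}{2-H_k-H_{\bar k}}$ and $H$ is the Shannon
  entropy of the min-max-normalised indicator shares (less uniform
  indicator → larger weight). The model input for $u$ is the 24-vector
  $[B(u), B(u_1), \dots, B(u_{23})]$ over $u$'s neighbours sorted by
  degree, zero-padded.
* **Propagation operator.** Relationship strength $R = (A+I)^2$, i.e.
  $R_{ij} = C_{ij} + 2$ on edges, $C_{ij}$ (common-neighbour count) on
  2-hop pairs and $k(i)+1$ on the diagonal; messages flow along
  $L = D^{-1/2} R D^{-1/2}$ with $D = \mathrm{diag}(\text{row sums of } R)$.
* **Network.** Input batch norm, two message-passing layers
  $e^{(l)} = \mathrm{BatchNorm}(e^{(l-1)} W_1 + L e^{(l-1)} W_2)$, and a
  fully connected layer to one score per node. MSE loss against SIR labels,
  NAdam, learning rate 0.001.
* **Evaluation.** Kendall $\tau$ (plain $\tau$-a,
  $\tau = (N_c - N_d) / \binom{n}{2}$) between a method's scores and SIR
  labels, swept over infection rates $\beta/\beta_{th} \in [1, 2]$ where
  $\beta_{th} = \langle k\rangle / \langle k^2\rangle$; classical baselines
  (degree, K-shell, betweenness, PageRank) use the same protocol.

Training data are synthetic: Barabási–Albert scale-free graphs and an
LFR-style community benchmark, both generated in-package. See the methods
vignette (`vignettes/relationship-strength-gnn.Rmd`) for assumptions,
parameter choices and limitations.

## Worked example

```r
library(rsgnn)

ba  <- generate_ba(400, 4, seed = 1)
lfr <- generate_lfr(400, tau1 = 3, tau2 = 1.5, mu = 0.1,
                    avg_deg = 8, max_deg = 40, seed = 2)
network_stats(ba)
#> n=400  |E|=1584  <k>=7.920  max_deg=68  C=0.077  r=-0.115
epidemic_threshold(ba)
#> [1] 0.06
entropy_weights(ba)
#> H_k=0.8233  H_kbar=0.9683  omega1=0.8477  omega2=0.1523

lab_ba  <- label_all_nodes(ba,  beta_ratio = 1, sn = 500, seed = 10)
lab_lfr <- label_all_nodes(lfr, beta_ratio = 1, sn = 500, seed = 11)
model <- rsgnn_train(list(list(network = ba,  labels = lab_ba),
                          list(network = lfr, labels = lab_lfr)),
                     epochs = 1000, seed = 42)

te     <- generate_ba(300, 4, seed = 3)          # held-out network
lab_te <- label_all_nodes(te, beta_ratio = 1, sn = 500, seed = 12)
head(rsgnn_rank(model, te), 3)
#>   node    score rank
#> 1    5 8.384162    1
#> 2    6 7.414028    2
#> 3    7 7.002220    3
evaluate_method(te, rsgnn_scores(model, te), lab_te, method = "RSGNN")
#>   method beta_ratio       tau       p_value n_nodes
#> 1  RSGNN         NA 0.8298551 6.357828e-102     300
evaluate_method(te, degree_centrality(te), lab_te)
#>   method beta_ratio       tau     p_value n_nodes
#> 1     DC         NA 0.5592419 2.70908e-47     300
```

The entropy weights say degree varies more informatively than neighbour
degree on this scale-free graph ($\omega_1 = 0.85$), the threshold 0.06 is
the infection probability used for labelling, and the transferred model
ranks the held-out network's spreaders far better than degree centrality
($\tau$ 0.83 vs 0.56; both p-values far below 0.01). Scores are on the
standardised label scale used in training; only their order matters.
`beta_sweep()` repeats
this comparison over $\beta/\beta_{th} \in \{1, 1.2, \dots, 2\}$ and
`ablation()` compares the entropy-weighted feature against its two
single-indicator variants.

## Command line

```sh
Rscript inst/cli/rsgnn.R generate --model ba --n 1000 --m 4 --seed 7 --out data/ba
Rscript inst/cli/rsgnn.R label    --graph data/ba.edgelist --beta-ratio 1 --sn 500 --seed 7 --out data/ba_labels.csv
Rscript inst/cli/rsgnn.R train    --graphs data/ba.edgelist --labels data/ba_labels.csv --seed 7 --out data/model.json
Rscript inst/cli/rsgnn.R rank     --model data/model.json --graph data/ba.edgelist --out data/rank.csv
Rscript inst/cli/rsgnn.R evaluate --graph data/ba.edgelist --model data/model.json \
    --methods rsgnn,dc,ks,bc,pr --sn 500 --seed 7 --out data/results.csv
```

Every command writes a `.config.json` snapshot next to its output; one
`--seed` reproduces the whole pipeline.

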