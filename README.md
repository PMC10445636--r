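# deeppotr

Deep Potential neural-network interatomic potentials in R, at desk scale.

Molecular simulation needs potential-energy surfaces that are both accurate
and cheap.  Machine-learning potentials get there by writing the total
energy of a configuration as a sum of atomic contributions,

    E = Σ_i E_i,    E_i = F( D(r_i, {r_j : j ∈ n(i)}) ),

where `n(i)` are the neighbors of atom *i* within a cutoff `r_c`, `D` is a
*descriptor* — a representation of the local environment that is invariant
under translation, rigid rotation and permutation of like atoms — and `F`
is a fitting network.  Forces are `F_i = −∂E/∂r_i` and the virial is the
cell derivative `Ξ_αβ = −Σ_γ (∂E/∂h_γα) h_γβ`, so a model trained on
energies and forces yields a complete, conservative force field.

`deeppotr` implements this model family end to end for people who want to
study, test or teach its machinery on a single CPU:

* **Descriptors** — local-frame; smooth two-body embedding (full
  `se_e2_a` and radial `se_e2_r`); three-body embedding `se_e3`;
  attention-based `se_atten`; and `hybrid` concatenations.  Multi-species
  parameter routing per species pair, per neighbor species, or through a
  shared type embedding.
* **Heads** — scalar energy (with optional atomic/frame parameters),
  vector and matrix tensor heads (exactly rotation-equivariant), analytic
  forces and virials from a built-in reverse-mode tape.
* **Trainer** — Adam with the exponentially decaying learning-rate
  schedule, composite energy/force/virial losses with schedule-interpolated
  prefactors, relative and atom-weighted force losses, deterministic
  seeding, and multi-task training with a shared descriptor.  Force-loss
  parameter gradients are exact (forward-over-reverse on the tape).
* **Concurrent learning** — ensemble model deviation of forces and
  virials, and threshold-based candidate selection.
* **Compression** — embedding networks tabulated as piecewise quintic
  Hermite polynomials (C², error ~ Δx⁶) with a merged, precisely indexed
  contraction.
* **Variants** — QM/MM range correction (MM–MM interactions and MM energy
  bias removed exactly), reciprocal-space long-range electrostatics of
  Gaussian charges, and smooth interpolation with a tabulated pairwise
  potential.
* **Data** — a per-system on-disk layout and a single-file container, both
  bit-exact round trips, plus a Lennard-Jones generator that produces
  exactly labeled synthetic training data so nothing has to be downloaded.

The methods vignette (`vignettes/deep-potential-methods.Rmd`) documents the
formulas, the numerical choices and the design decisions in detail.

## Worked example

Generate labeled Lennard-Jones data, train a small smooth-embedding model,
predict, and use a two-model ensemble for candidate selection:

```r
library(deeppotr)

ds <- gen_lj_dataset(lj_spec(), n_frames = 60, seed = 7)
sp <- split_dataset(ds, val_fraction = 0.1, seed = 1)

model <- energy_model(
  type_map   = "Ar",
  descriptor = descriptor_config("se_e2_a", rcut = 5.5, rcut_smth = 2.0,
                                 sel = 16, neuron = c(10, 20),
                                 axis_neuron = 4),
  fitting    = fitting_config(neuron = c(32, 32)),
  seed       = 1)

fit <- train_model(model, sp$train,
                   sch  = lr_schedule(5e-3, 5e-5, 60, 3000),
                   spec = loss_spec(batch_size = 2),
                   tau_stop = 3000, seed = 2, validation = sp$val)
fit$validation
#>   step      rmse_e     rmse_f
#> 1    0 0.602489659 0.19674137
#> 2 2999 0.007925108 0.06179185
```

Validation RMSEs are eV/atom (energy) and eV/Å (forces): three thousand
steps take this small model from untrained (force errors the size of the
forces themselves, 0.20 eV/Å) to qualitatively correct (0.06 eV/Å);
the full-size recovery run in the acceptance script trains longer and gets
much further.  Predictions for a held-out frame:

```r
fr <- sp$val$frames[[1]]
p <- predict_frame(fit$model, fr$frame)
round(p$energy, 4); round(fr$labels$energy, 4)
#> [1] 0.5063
#> [1] 0.3736
round(cbind(predicted = p$forces[1:3, 1], reference = fr$labels$force[1:3, 1]), 4)
#>      predicted reference
#> [1,]   -0.5685   -0.4387
#> [2,]    0.7461    0.6327
#> [3,]    0.1451    0.1066
```

An independently initialized second model gives an ensemble; frames whose
maximum per-atom force deviation falls between the thresholds are the
candidates a concurrent-learning loop would send for labeling:

```r
model2 <- energy_model("Ar", model$descriptor,
                       fitting_config(neuron = c(32, 32)), seed = 9)
fit2 <- train_model(model2, sp$train, lr_schedule(5e-3, 5e-5, 60, 3000),
                    loss_spec(batch_size = 2), tau_stop = 3000, seed = 4)
dv <- model_deviation(list(fit$model, fit2$model), sp$val)
round(head(dv$table, 3), 4)
#>   frame max_devi_f min_devi_f avg_devi_f max_devi_v min_devi_v avg_devi_v
#> 1     0     0.0385     0.0015     0.0090     0.0054      7e-04     0.0027
#> 2     1     0.0092     0.0002     0.0042     0.0068      6e-04     0.0028
#> 3     2     0.0156     0.0010     0.0073     0.0085      1e-04     0.0031
select_candidates(dv$table$max_devi_f, theta_low = 0.02)
#> $candidates
#> [1] 1
#> $accurate_ratio
#> [1] 0.8333333
```

## Command line

A thin `dp` launcher (`inst/exec/dp`, or call `dp_main()` in R) wraps the
same functions:

```sh
dp gen-data lj -o data/lj --n-frames 100 --seed 1
dp train input.json -o model.dpr
dp test -m model.dpr -s data/lj -n 20
dp compress -i model.dpr -o model-c.dpr -s data/lj --stride 1024
dp devi -m m1.dpr m2.dpr -s data/lj -o devi.out
```

`dp test` prints energy RMSE/atom (meV/atom), force RMSE (meV/Å) and
virial RMSE/atom (meV/atom).  The training configuration is a JSON (or
YAML) document; `parse_config()` validates it and reports unknown keys with
their location.

## Data formats

A *system* is a set of frames sharing one species vector.  The directory
layout holds `type_map.raw`, `type.raw` and a `set.000/` of full-precision
text matrices — `coord` (Nf×3N), `box` (Nf×9), `energy` (Nf×1), `force`
(Nf×3N), `virial` (Nf×9), and optional `delta_energy`, `atomic_tensor`,
`aparam`, `fparam`:

```
data/lj/
├── type_map.raw        # one species name per line
├── type.raw            # per-atom 0-based species indices
└── set.000/
    ├── coord.txt  box.txt  energy.txt  force.txt  virial.txt
```

`write_system(..., format = "container")` stores the same arrays for one or
more systems in a single serialized file.  Both formats round-trip all
numeric payloads bit-exactly.  Units are fixed to eV and Å throughout.

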