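"""Batch coalescent simulation backend.

Reads a JSON batch description, simulates every scenario with msprime and
writes all resulting haplotype alignments to a single plain-text file.

Scaling convention (fixed here and mirrored by the R wrapper): haploid
samples with a reference population size of 0.5, so that

    per-bp recombination rate passed to msprime  == rho  (= 4*Ne*r)
    per-bp mutation rate passed to msprime       == theta (= 4*Ne*mu)
    1 coalescent time unit (2*Ne generations)    == 0.5 generations

Population-size histories arrive already converted to msprime units
(absolute sizes, times in generations) by the caller.

Usage: python coalsim.py <batch.json> <out.txt>
"""

import json
import sys

import msprime
import numpy as np


def simulate_one(sc):
    L = int(sc["length_bp"])
    breaks = list(sc["breaks"]) + [L]
    rate_map = msprime.RateMap(position=[float(b) for b in breaks],
                               rate=[float(r) for r in sc["rates"]])
    demography = msprime.Demography()
    sizes = sc.get("pop_sizes") or [0.5]
    times = sc.get("pop_times") or []
    demography.add_population(initial_size=float(sizes[0]))
    for t, s in zip(times, sizes[1:]):
        demography.add_population_parameters_change(
            time=float(t), initial_size=float(s))
    ts = msprime.sim_ancestry(
        samples=int(sc["n"]),
        ploidy=1,
        demography=demography,
        recombination_rate=rate_map,
        sequence_length=L,
        discrete_genome=True,
        random_seed=int(sc["seed"]))
    mts = msprime.sim_mutations(
        ts, rate=float(sc["theta"]),
        model=msprime.BinaryMutationModel(),
        random_seed=int(sc["seed"]) + 1)
    G = mts.genotype_matrix()           # S x n, entries 0/1
    pos = np.array([int(s.position) for s in mts.sites()], dtype=int)
    if G.shape[0] > 0:                  # drop monomorphic columns
        poly = (G.sum(axis=1) > 0) & (G.sum(axis=1) < G.shape[1])
        G = G[poly]
        pos = pos[poly]
    return pos, G


def main(batch_path, out_path):
    with open(batch_path) as fh:
        batch = json.load(fh)
    with open(out_path, "w") as out:
        for sc in batch["scenarios"]:
            pos, G = simulate_one(sc)
            out.write("#scenario %s %d %d %d\n"
                      % (sc["id"], int(sc["n"]), int(sc["length_bp"]),
                         G.shape[0]))
            if G.shape[0] > 0:
                out.write("@" + " ".join(str(p) for p in pos) + "\n")
                for hap in G.T:
                    out.write("".join("1" if a else "0" for a in hap) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
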