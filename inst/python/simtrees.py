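"""Coalescent simulation backend.

Reads a JSON job description and writes, into the job's output directory,
consolidated tab-separated tables across replicates:

  params.tsv       replicate parameter draws and task targets
  nodes.tsv        rep, id, time, population, is_sample
  edges.tsv        rep, left, right, parent, child
  mutations.tsv    rep, position, node
  trees.tsv        rep, num_trees (the simulator's own tree count)
  ms.txt           ms-style genotype output, one "//" block per replicate

Population sizes in job parameters are diploid; simulations run with
ploidy = 1 and haploid size 2N so that arbitrary haploid sample counts are
possible while keeping the standard diploid time scale (pairwise coalescence
expectation 2N generations, rho = 4 N r L).
"""
import json
import math
import sys

import msprime
import numpy as np


def trunc_exp(rng, mean, low, high):
    """Inverse-CDF draw from an exponential truncated to [low, high]."""
    a = math.exp(-low / mean)
    b = math.exp(-high / mean)
    u = rng.uniform(0.0, 1.0)
    return min(max(-mean * math.log(a - u * (a - b)), low), high)


def sim_one(task, params, rng, seed):
    mu = params["mu"]
    L = params["L"]
    if task == "recombination":
        N = float(rng.choice(np.atleast_1d(params["N_set"])))
        r = trunc_exp(rng, params["r_mean"], params["r_low"], params["r_high"])
        ts = msprime.sim_ancestry(
            samples=int(params["n"]), ploidy=1, population_size=2 * N,
            sequence_length=L, recombination_rate=r, random_seed=seed)
        meta = {"N": N, "r": r, "log_r": math.log(r)}
        target = [math.log(r)]
    elif task == "demography":
        N0 = rng.uniform(100, 4e4)
        T1 = rng.uniform(100, 3500)
        N1 = rng.uniform(100, 5000)
        T2 = T1 + rng.uniform(1, 3500)
        N2 = rng.uniform(100, 2e4)
        dem = msprime.Demography()
        dem.add_population(name="pop0", initial_size=2 * N0)
        dem.add_population_parameters_change(time=T1, initial_size=2 * N1,
                                             population="pop0")
        dem.add_population_parameters_change(time=T2, initial_size=2 * N2,
                                             population="pop0")
        ts = msprime.sim_ancestry(
            samples={"pop0": int(params["n"])}, ploidy=1, demography=dem,
            sequence_length=L, recombination_rate=params["r"],
            random_seed=seed)
        meta = {"N0": N0, "T1": T1, "N1": N1, "T2": T2, "N2": N2}
        target = [N0, T1, N1, T2, N2]
    elif task == "introgression":
        cls = int(params["cls"])  # 0: A->B (forward), 1: B->A, 2: none
        T = params["T_split"]
        t_mig = rng.uniform(params["t_frac"][0], params["t_frac"][1]) * T
        dem = msprime.Demography()
        dem.add_population(name="A", initial_size=2 * params["N"])
        dem.add_population(name="B", initial_size=2 * params["N"])
        dem.add_population(name="anc", initial_size=2 * params["N"])
        if cls == 0:
            # forward-time pulse A -> B: backwards, lineages in B jump to A
            dem.add_mass_migration(time=t_mig, source="B", dest="A",
                                   proportion=params["pulse_prop"])
        elif cls == 1:
            dem.add_mass_migration(time=t_mig, source="A", dest="B",
                                   proportion=params["pulse_prop"])
        if cls == 2:
            t_mig = -1.0  # no admixture event in the provenance log
        dem.add_population_split(time=T, derived=["A", "B"], ancestral="anc")
        dem.sort_events()
        ts = msprime.sim_ancestry(
            samples={"A": int(params["n1"]), "B": int(params["n2"])},
            ploidy=1, demography=dem, sequence_length=L,
            recombination_rate=params["r"], random_seed=seed)
        meta = {"cls": cls, "t_mig": t_mig}
        target = [cls]
    else:
        raise SystemExit(f"unknown task: {task}")
    ts = msprime.sim_mutations(ts, rate=mu, random_seed=seed + 1,
                               model=msprime.BinaryMutationModel(),
                               discrete_genome=False)
    return ts, meta, target


def write_ms_block(fh, ts, L):
    fh.write("//\n")
    m = ts.genotype_matrix()  # sites x samples
    pos = [s.position / L for s in ts.sites()]
    fh.write(f"segsites: {m.shape[0]}\n")
    if m.shape[0]:
        fh.write("positions: " + " ".join(f"{p:.6f}" for p in pos) + "\n")
        for hap in m.T:
            fh.write("".join("1" if g else "0" for g in hap) + "\n")
    fh.write("\n")


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    task = job["task"]
    params = job["params"]
    n_reps = int(job["n_reps"])
    seed = int(job["seed"])
    out = job["out_dir"]
    write_ms = bool(job.get("write_ms", True))
    rng = np.random.default_rng(seed)
    L = params["L"]

    nodes_fh = open(f"{out}/nodes.tsv", "w")
    edges_fh = open(f"{out}/edges.tsv", "w")
    muts_fh = open(f"{out}/mutations.tsv", "w")
    trees_fh = open(f"{out}/trees.tsv", "w")
    params_fh = open(f"{out}/params.tsv", "w")
    ms_fh = open(f"{out}/ms.txt", "w") if write_ms else None
    header_done = False
    for rep in range(1, n_reps + 1):
        if task == "introgression":
            params["cls"] = (rep - 1) % 3
        rep_seed = (seed * 48271 + rep * 16807) % 2147483629 + 1
        ts, meta, target = sim_one(task, params, rng, rep_seed)
        if not header_done:
            cols = list(meta.keys())
            params_fh.write("rep\t" + "\t".join(cols) +
                            "\t" + "\t".join(f"target{i+1}" for i in range(len(target))) + "\n")
            header_done = True
        params_fh.write(f"{rep}\t" + "\t".join(f"{meta[c]:.10g}" for c in cols) +
                        "\t" + "\t".join(f"{t:.10g}" for t in target) + "\n")
        for nid, node in enumerate(ts.nodes()):
            is_s = 1 if (node.flags & 1) else 0
            nodes_fh.write(f"{rep}\t{nid}\t{node.time:.12g}\t{node.population}\t{is_s}\n")
        for e in ts.edges():
            edges_fh.write(f"{rep}\t{e.left:.8f}\t{e.right:.8f}\t{e.parent}\t{e.child}\n")
        for site in ts.sites():
            for mut in site.mutations:
                muts_fh.write(f"{rep}\t{site.position:.8f}\t{mut.node}\n")
        trees_fh.write(f"{rep}\t{ts.num_trees}\n")
        if ms_fh:
            write_ms_block(ms_fh, ts, L)
    for fh in (nodes_fh, edges_fh, muts_fh, trees_fh, params_fh):
        fh.close()
    if ms_fh:
        ms_fh.close()


if __name__ == "__main__":
    main(sys.argv[1])
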