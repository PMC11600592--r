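"""Dump a binary succinct tree-sequence (.trees) file as the text table
dialect read by load_tree_sequence(dialect = "tables"): sections #nodes
(id, time, population, is_sample), #edges (left, right, parent, child) and
#mutations (position, node), with a #L header carrying the locus length.

Usage: python dump_trees.py input.trees output.txt
"""
import sys

import tskit


def main(inp, outp):
    ts = tskit.load(inp)
    with open(outp, "w") as fh:
        fh.write("# succinct tree-sequence table dump\n")
        fh.write(f"#L\t{ts.sequence_length:.10g}\n")
        fh.write("#nodes\n")
        for nid, node in enumerate(ts.nodes()):
            is_s = 1 if (node.flags & 1) else 0
            fh.write(f"{nid}\t{node.time:.12g}\t{node.population}\t{is_s}\n")
        fh.write("#edges\n")
        for e in ts.edges():
            fh.write(f"{e.left:.8f}\t{e.right:.8f}\t{e.parent}\t{e.child}\n")
        fh.write("#mutations\n")
        for site in ts.sites():
            for mut in site.mutations:
                fh.write(f"{site.position:.8f}\t{mut.node}\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
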