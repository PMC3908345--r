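LOCUS       TESTPLA01               2000 bp    DNA     circular BCT 01-JAN-2020
DEFINITION  Synthetica prima strain T1 plasmid pT1A, complete sequence.
ACCESSION   TESTPLA01
VERSION     TESTPLA01.1
SOURCE      Synthetica prima
  ORGANISM  Synthetica prima
            Bacteria; Synthetica.
FEATURES             Location/Qualifiers
     source          1..2000
                     /organism="Synthetica prima"
                     /plasmid="pT1A"
     CDS             150..600
                     /locus_tag="P1_0001"
                     /product="replication initiator RepA"
                     /protein_id="PP_0001.1"
                     /translation="MSDLIVKDNALINASYNLDLVEQRLILLAIVEARESGKGINAND
                     PLTVHAESYINQFGVHRNTAYQALKDACKDLFARQFSYQEKKANGNIRNVMSRWVSQI"
     CDS             700..1100
                     /locus_tag="P1_0002"
                     /product="mobilization protein MobA"
                     /protein_id="PP_0002.1"
                     /translation="MAIYHLSVKTISRSSGRSAVASAAYRSGEKLVCDFYGKEQDYTK
                     KTGVEYTEIYAPENAPEWMKNREKLWNEVEKVEKRKNSQVAREFEIALPAELNAEQRL"
ORIGIN
//
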