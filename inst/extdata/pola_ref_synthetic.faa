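>POLA_REF_SYNTH synthetic stand-in for E. coli K-12 DNA polymerase I (928 aa; anchors R688 D705 K758 F762; Klenow-like domain 324-928)
FRAVKSISGQVATPWNLFCSISRKPSDSKENKNEEYEWMVETRARQSLNIPVKKLTDLWK
EKGKKIGIHLAKMAGLVDKEADAPADSIVFAFNRFRSSQEDLGITQEGRRKIPASDTQGH
LCGLEDMTGSDMRQPGHMEHHLSFGLGDQDDDASIRLRKTHKVRGNPYVESYDEWFYRLN
LTLVQDNNVMLQGMRPMNSGDDIGKRATAWEPWDTVRRGEATDDTEMTNEAKSAAPLEEG
VDFPKSPVFGEIDSIGDIHVFYKRCTADRLVKGLADVRLGASRLYKKKENDVEPVTLALQ
QRAIGRASDAHVADTELEYMLSLLALNWANLMGSKQNKSERIDGGIEKVASLGKKWNIMF
NITARDQLLAMTPFWDTIKVIKEDILMAPPQCGPIEETQTRPPHVYVFEMAVLPSKVAVW
EAGRMLFYVMLVRDMEGGCSPTVIFEKFNPEPGDSSEAQIRKPAIDTSTPAMTSLLDCIS
LEGIEMPYGLMGLSQLGLNTGQEFIHGNHLNVFTTEYVALSILRTPVMYDSDVRLDDPAI
ILYDIWSGICIQLIDAMEDSHKVQRTGVEKEPRAPESAIIAPDYMRTVADFDTGPLYCTE
VLTQDGPKNSDSNRTGPPVAPPLVSGGLGVWRRNAATGSNKHCILMIAHAIAVNEAQTWR
IGIMGLCVQLKFTGVTQGILYKSVVRTRLSSQGSISREFRSVWADYQGENPLPRSRIDCQ
DVLAHRLKGTLAGGVDALFLILYKGAKLMALGSEMAQKTSDFLVKPEVVLQNRIMDVGVM
MIAGKTVVYRKEMYPSASFLRTYKVVELNPPKLHSGNANEPLREDGTGSAYSPEIELSGT
GTSESGRELAGEQTVIGQSHANVDQAHERLDVKLREQHHVETLTKLGLVETSMLAEDRTS
TIGNLVVNVEYAGAPKKSVESIPVVFRA
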