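protein_id	position	peptide	label
SYN00001	10	YWCMYVLQEYAHGEVHNYE	1
SYN00002	10	YNNHWDLDEYLSEGVYDAQ	1
SYN00003	10	HWQTFVRREYRFNHCLAMI	1
SYN00004	10	VLLINNFIEYWIRCVNFIW	1
SYN00005	10	QFWNNMVFPYDHQWMFTDG	1
SYN00006	10	NLEMFCYGSYDKALGRFQI	1
SYN00007	10	SAATNPTKLYQMQRITLYH	1
SYN00008	10	EMHFGSNRAYDKHIETFVS	1
SYN00009	10	RHDLHGHDEYFSVLLGSNC	1
SYN00010	10	SHKNNVRDEYKITVDGVEL	1
SYN00011	10	MNEMFLYHKYHRVMWQAVL	1
SYN00012	10	SQPNYPAIKYEKPINTCWQ	1
SYN00013	10	YIGRMFDEEYPMCTEVPAV	1
SYN00014	10	HDSKQFKDEYRPMAWVLDP	1
SYN00015	10	MMEVSFVESYDKALKEHWW	1
SYN00016	10	YVFYQVNDEYDHTREHIFH	1
SYN00017	10	APHEYEISYYFWRNAVYKA	1
SYN00018	10	EKTGDHLDRYREVEYEYAT	1
SYN00019	10	MNLMCTCKEYTVHCDCALQ	1
SYN00020	10	PWDINHVDEYAPICWLTWV	1
SYN00021	10	YMEMGWCKEYKGEAHPFFE	1
SYN00022	10	EFMPQCRMAYNPPIQNHFH	1
SYN00023	10	ANAGKIPDEYKTVTMYTGR	1
SYN00024	10	YAVSCIITDYEETGNHVCI	1
SYN00025	10	DINFCEAMVYDKQTPSPRW	1
SYN00026	10	NVDRAKVAEYDEEKWFECR	1
SYN00027	10	KIMHGMQHEYDKWCHVTKA	1
SYN00028	10	YFILCCEDEYDKYQHTDAE	1
SYN00029	10	LCRSGAWDEYDKMMKHSST	1
SYN00030	10	VGNMDYPWIYVMFHIFVYP	1
SYN00031	10	SKNIGATDEYDELIWQMTY	1
SYN00032	10	VFNGLFCYGYDKADLQNGH	1
SYN00033	10	KILGCCHYEYETADLWRQR	1
SYN00034	10	RCDGKETDEYDRNYLQCDF	1
SYN00035	10	CAYPPKVDEYCGCTPDEIE	1
SYN00036	10	VVCSQNNRTYDAHAPWRAG	1
SYN00037	10	CDLEHYQHEYDSRWQVDDF	1
SYN00038	10	GWGNRQMAFYDPYAVMIVD	1
SYN00039	10	YPDWYMPEEYDAQHRDTNA	1
SYN00040	10	QLMSCDEIYYEYNTNCIGH	1
SYN00041	10	KDRITYVQCYDKRLRINET	1
SYN00042	10	LPYEVILGEYCDAKCSWLK	1
SYN00043	10	CDKPDKTYLYMYSANALSH	1
SYN00044	10	AGWVPQAPCYTFINVMIYT	1
SYN00045	10	LNINNSHDEYYYKCGRCTG	1
SYN00046	10	AMMREFVQFYDKIEAYKVE	1
SYN00047	10	WFEMHPRDEYDKWTMMHQF	1
SYN00048	10	QEVKKVTWYYFCLVCSHEY	1
SYN00049	10	AMRAVAFDEYILCKFVPEP	1
SYN00050	10	QYDYFCTWEYLQDCYCQQS	1
SYN00051	10	IILGNVSYEYRGGMNLIGL	1
SYN00052	10	IFKATGTPCYRCRDRNRWG	1
SYN00053	10	KHRWHEIDEYFHMHKSNIF	1
SYN00054	10	TNRRLRDDEYTVLYTETTA	1
SYN00055	10	CCLNRHRECYDSPWMKQPW	1
SYN00056	10	STIMCVCYSYRNCAHCMVD	1
SYN00057	10	REHGPQQGNYDFREECLAN	1
SYN00058	10	FNREYNHCKYDKSNVTIHW	1
SYN00059	10	HPWMLCKGMYFLSVKRRFT	1
SYN00060	10	NQVIYHYGEYPPPATCCSD	1
SYN00061	10	RSKTACRPMYQLDYEILCK	0
SYN00062	10	AEDYRWSRAYFYPFNYVAS	0
SYN00063	10	TIVIHESMSYNMNDIHKMP	0
SYN00064	10	PYDVGDGERYPQMVWKVCN	0
SYN00065	10	VNEGIKLQMYQPRESNKGV	0
SYN00066	10	FEQTWRPQDYVRLKTHSEH	0
SYN00067	10	HWIPDWWHTYNYYSPYSCT	0
SYN00068	10	VGFLFGPGIYGCGDMFIYF	0
SYN00069	10	RYKVMKYKCYHIMFVQTFV	0
SYN00070	10	GWWHIQKIQYVVTKYCVAP	0
SYN00071	10	CEIMVPHTEYLGYGRVAKC	0
SYN00072	10	ETCTWCSGFYRKTLSRWYN	0
SYN00073	10	GMYDCMGMQYYTKINSFEP	0
SYN00074	10	MEAKVYLVFYPCWELCPWS	0
SYN00075	10	FWMDLGRHKYMQMKVNGTL	0
SYN00076	10	SIMERRRMGYMPEPDQMQS	0
SYN00077	10	CIPGEYFVVYDPPTWSSVH	0
SYN00078	10	KLYHMCSICYAPFNSECNY	0
SYN00079	10	NMFHYEINFYFSIHDLYKH	0
SYN00080	10	CKTKPEKTYYNTTYERYWY	0
SYN00081	10	PMGMYLTFTYEDTNVEWDA	0
SYN00082	10	FCPWTAKAVYGSVWETQDE	0
SYN00083	10	KFVSQKHAHYFWDTTQISR	0
SYN00084	10	QAEATSHNEYRSIRGPRAY	0
SYN00085	10	TIWIYSCEEYERMDVCGFL	0
SYN00086	10	PFMVFCRPLYHAFTCCVLM	0
SYN00087	10	GMWEFYSCKYCVHGFFAGV	0
SYN00088	10	DCGEDNQAEYGYQEMDMYR	0
SYN00089	10	DIDSVRDCNYSHHVAMYPH	0
SYN00090	10	ICCNVCNPSYCPEAFAFKQ	0
SYN00091	10	RWAQHYDSEYSCWKCLPFP	0
SYN00092	10	CSMELCHFKYQLRDEYKAN	0
SYN00093	10	GIVWQTCHGYLIWCNIAKY	0
SYN00094	10	YKLVKNSLWYIGALIMFMI	0
SYN00095	10	YIMCKHTKEYGFYFNVMGK	0
SYN00096	10	SDFSYNERVYTVCDSVSII	0
SYN00097	10	ITTNKNPQVYGAKTLEGRG	0
SYN00098	10	NQIYDDKSCYGFHINELTY	0
SYN00099	10	SEFYSYRITYRINITCMFH	0
SYN00100	10	QCCMRPKEHYMMTASSMHA	0
SYN00101	10	QMETDDVDFYPLDINTNFE	0
SYN00102	10	GLFNCRAADYLVYRGGKPW	0
SYN00103	10	GDNGLQMCSYRWILGNDFP	0
SYN00104	10	KIVSCDDYMYQMLKQFWYV	0
SYN00105	10	YWETPLEKKYNSATYMLNQ	0
SYN00106	10	AYWSYQWRQYHRNTYNECM	0
SYN00107	10	SKPFIVSPEYSSIIKIIWV	0
SYN00108	10	SFEHGKWHDYVAQHESLFE	0
SYN00109	10	NIYINTYCRYRAERSCRFA	0
SYN00110	10	CIHPEWMLTYNAWSMHDPN	0
SYN00111	10	QEFWKQDQKYSPNSHFHPY	0
SYN00112	10	VATWIKSCTYAYVLVHMAN	0
SYN00113	10	TMGKYYHRVYRAWFERRHE	0
SYN00114	10	MDISYSIEWYAAKEPVMTP	0
SYN00115	10	NGNTTDKYLYAQDMHNSEA	0
SYN00116	10	NYISTEIEDYTFIYYAQGM	0
SYN00117	10	CHFKAVDPWYEDKHEDKWP	0
SYN00118	10	KRHHPTPHHYFLQMYNNQY	0
SYN00119	10	QYKDGDTPIYYCRRSSMHI	0
SYN00120	10	VAPREYNAVYMAGLHESRY	0
SYN00121	10	KLVFTSHSPYKSADDTAYA	0
SYN00122	10	LKYQAYLLRYIVCESLMMV	0
SYN00123	10	PEVEANWMQYMFHYFLYGR	0
SYN00124	10	PHEKEIYRGYYVIYFSNNG	0
SYN00125	10	SPQIQVNMQYNNYYNMYSA	0
SYN00126	10	KYRVWTTHMYYWQEIEYFP	0
SYN00127	10	YKCKENTNPYIAIFCYNWM	0
SYN00128	10	AVYLKTVSVYITPRVGTQY	0
SYN00129	10	GSMLFDYTMYCQFHIRGAG	0
SYN00130	10	STHQLMLVDYMAMVMWYFS	0
SYN00131	10	YYWLMCQIMYKKEFKWSGC	0
SYN00132	10	QCGAASGWPYEGDYRATVG	0
SYN00133	10	QFTAYSWIYYNCLLYMNNW	0
SYN00134	10	YKQYYCYRCYVKNWTDIEK	0
SYN00135	10	WRLDTMPFVYCGMIKYAVF	0
SYN00136	10	PMDMDPRADYSIQWEINVF	0
SYN00137	10	VNCICHDFHYSHKNIMCIV	0
SYN00138	10	EINRIDGFVYWHAQHPCYV	0
SYN00139	10	TVNQGKNQYYHTWCHVLSN	0
SYN00140	10	QHGWTNNSDYELCLTQPWH	0
SYN00141	10	ELSYMHTYPYYRPPRKYIR	0
SYN00142	10	DDAPNYHTCYQAFEMMLAV	0
SYN00143	10	MTNNDLRFHYQNMNKECEW	0
SYN00144	10	TKFYISPHFYIFQPHGVCY	0
SYN00145	10	SCPWTFLLPYGPHDHVKCI	0
SYN00146	10	VCTLKGWVDYVRESMVSGV	0
SYN00147	10	FARDCCEFLYPKDQKAQRI	0
SYN00148	10	YKGTSIIRPYYAAFCSWCI	0
SYN00149	10	HVIYPLSVNYQNCNWKLKL	0
SYN00150	10	EYIKDENRHYGCWTENANE	0
SYN00151	10	SLYGIWFKFYVQPLYYFAW	0
SYN00152	10	IPFDLCRWSYRVRIPPFEG	0
SYN00153	10	TDRKIAEPGYLRNMHLMEI	0
SYN00154	10	KFEFSVHMPYEFGQCGMQN	0
SYN00155	10	RSEEKNSQYYCAYQNVYIL	0
SYN00156	10	TMDHQYCSGYSYPNMMMMK	0
SYN00157	10	FRYPQMEEVYDEQQKFDTT	0
SYN00158	10	CAHEVNLLIYDTNKPSHCW	0
SYN00159	10	EMWARVPMFYFYTIAQYKT	0
SYN00160	10	RMTYRFFPNYAQTCDEARN	0
SYN00161	10	YPTALNNLFYRSNWSGVRT	0
SYN00162	10	PRGSRLVAGYAMINTNFYC	0
SYN00163	10	QHCECIDTAYKDGMCDEYN	0
SYN00164	10	FACCVLMFFYVCLEGELHV	0
SYN00165	10	NQHRDCWEAYHKQLISDAT	0
SYN00166	10	FPIRYGLSYYMFRGPWQDA	0
SYN00167	10	MQSYDEHEGYFHQVCYNNQ	0
SYN00168	10	IYHLFKDAKYSGSVDHPWI	0
SYN00169	10	EKNLTRWTDYPFGVMGQGH	0
SYN00170	10	FHTNGLELWYGWKALGMPQ	0
SYN00171	10	SDQLLDIHAYFDMGTFWEA	0
SYN00172	10	LIGDLRRAPYDLIVWFLYL	0
SYN00173	10	LTAKQWHHPYIIAFFEMHC	0
SYN00174	10	MECFPWLESYQLVHTRNHE	0
SYN00175	10	LSGSDDMNPYFIEGDIRIV	0
SYN00176	10	EAQCFCGRFYCGMQGKHGI	0
SYN00177	10	VGCYHLKKNYDKYEWSYEQ	0
SYN00178	10	PECYKADEMYFMEQVHIWL	0
SYN00179	10	TDQTSMKAYYVCLCFTWSN	0
SYN00180	10	TVPAEAADMYKCDQADVYI	0
SYN00181	10	YPGQLMFQLYDRYQVRTYH	0
SYN00182	10	WMYRCEWFDYWVVMLYYEQ	0
SYN00183	10	IKRKMPEPYYNTFLPTQIK	0
SYN00184	10	HHQDTGFEIYVTQEWSFSD	0
SYN00185	10	SPGRMSSVLYHTMSVIQEA	0
SYN00186	10	SVMEGTHIKYTYQSSQMSV	0
SYN00187	10	YDAHWLGMRYETQMVLWEM	0
SYN00188	10	TAAQEMPFPYGLWHLITQF	0
SYN00189	10	EFMKHLDNFYQPMRWTWTK	0
SYN00190	10	HDSDWYMMIYWTYEYCQPL	0
SYN00191	10	FWIWTPIEPYQYSIWKMNF	0
SYN00192	10	TNVKDRWTTYLETQCIYHR	0
SYN00193	10	ERLRVIGCWYWFLFQFQCI	0
SYN00194	10	EGACWDNFSYYTCLMQHIT	0
SYN00195	10	DSVPEYCELYQEWTPDAMM	0
SYN00196	10	DMMHERNNCYDQIIWGIDD	0
SYN00197	10	NANKNCKNYYLQPTFAYND	0
SYN00198	10	EYIEDECCEYKWCETERAF	0
SYN00199	10	SPDVMVPFAYARTCECFFW	0
SYN00200	10	SDMECLLPDYMVWITWKYL	0
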