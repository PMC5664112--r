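node	parent	variants
ROOT		
L3	ROOT	769G,1018A,2758A,2885T,3594G,4104T,7146A,7256T,8468A,9042T,13650C,16278T
N	L3	8701A,9540A,10398A,10873A,15301T
R	N	12705G,16223T
U	R	12308A,12372A
U1	U	14070C,15148G,16249T
U1a	U1	285A,1709C,13104T,16189A
U1a1	U1a	385G,980C,5198T,9667T,13422A,16093T
U1a1a	U1a1	627T,1290G,2218T,4811G,6026A,6371T,7581C,8155G,8901A,10750A,11065G,12358G,13734G,14364A,15954C,16327C,3158.1T
U1a1a1	U1a1a	11467G
H	R	2706G,7028A
K	U	1811T,9055C,14167A
T2	R	709A,1888G,4917A,8697G,10463G,13368T,14905T,15607G,16294G
J	R	4216A,13708C,16069A,10398C!
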