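code,side,label
101,front,Top of the Head
102,front,Top of the Head
103,front,Face
104,front,Face
105,front,Neck
106,front,Neck
107,front,Right Shoulder
108,front,Chest
109,front,Chest
110,front,Left Shoulder
111,front,Right Upper Arm
112,front,Left Upper Arm
113,front,Right Elbow
114,front,Left Elbow
115,front,Right Forearm
116,front,Abdomen
117,front,Abdomen
118,front,Left Forearm
119,front,Right Wrist
120,front,Right Hip
121,front,Pelvis
122,front,Pelvis
123,front,Left Hip
124,front,Left Wrist
125,front,Right Hand
126,front,Right Upper Leg
127,front,Left Upper Leg
128,front,Left Hand
129,front,Right Knee
130,front,Left Knee
131,front,Right Lower Leg
132,front,Left Lower Leg
133,front,Right Ankle
134,front,Left Ankle
135,front,Right Foot
136,front,Left Foot
201,back,Top of the Head
202,back,Top of the Head
203,back,Back of the Head
204,back,Back of the Head
205,back,Neck
206,back,Neck
207,back,Left Shoulder
208,back,Upper Back
209,back,Upper Back
210,back,Right Shoulder
211,back,Left Upper Arm
212,back,Mid-Back
213,back,Mid-Back
214,back,Right Upper Arm
215,back,Left Elbow
216,back,Right Elbow
217,back,Left Forearm
218,back,Lower Back
219,back,Lower Back
220,back,Right Forearm
221,back,Left Wrist
222,back,Left Hip
223,back,Buttocks
224,back,Buttocks
225,back,Right Hip
226,back,Right Wrist
227,back,Left Hand
228,back,Left Upper Leg
229,back,Right Upper Leg
230,back,Right Hand
231,back,Left Knee
232,back,Right Knee
233,back,Left Lower Leg
234,back,Right Lower Leg
235,back,Left Ankle
236,back,Right Ankle
237,back,Left Foot
238,back,Right Foot
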